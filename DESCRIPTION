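Package: srtkit
Title: Latency-Corrected Stretch Reflex Threshold Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify stretch hyperreflexia from passive-stretch
    dynamometry: band-pass filtering and background-activation rejection of
    surface EMG, automatic stretch-reflex EMG onset detection by an
    approximated generalized likelihood-ratio (AGLR) variance-change test
    with a sustained-threshold fallback, H-reflex latency estimation from
    stimulus-locked traces, computation of the stretch reflex threshold
    (SRT) with and without individual reflex-latency correction, per-subject
    velocity-SRT regressions with tonic stretch reflex threshold (TSRT)
    extrapolation and velocity-dependence classification, and the associated
    group-level statistics (routed paired tests with Hedges' g, Friedman
    velocity effects with Bonferroni post hocs). Includes a synthetic
    dynamometer + EMG generator with known ground truth so every stage of
    the pipeline is verifiable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
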