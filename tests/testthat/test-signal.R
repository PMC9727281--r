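test_that("band-pass keeps the EMG band and rejects out-of-band components", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  s10 <- sin(2 * pi * 10 * t)
  s100 <- sin(2 * pi * 100 * t)
  expect_lt(rms(bandpass_emg(s10, fs)) / rms(s10), 0.10)
  expect_gt(rms(bandpass_emg(s100, fs)) / rms(s100), 0.90)
  expect_equal(bandpass_emg(rep(0, 1000), fs), rep(0, 1000))
})

test_that("filtering refuses traces shorter than three filter orders", {
  expect_error(bandpass_emg(rnorm(10), 2000), "too short")
  expect_error(bandpass_emg(rnorm(1000), 300, filter_spec(20, 195)), "Nyquist")
})

test_that("sliding RMS matches a direct windowed computation", {
  set.seed(1)
  x <- rnorm(50)
  fs <- 100
  got <- sliding_rms(x, fs, window = 0.1)   # 10-sample windows
  want <- sapply(10:50, function(k) sqrt(mean(x[(k - 9):k]^2)))
  expect_equal(got, want)
  expect_error(sliding_rms(x[1:5], fs, 0.1), "shorter")
})

test_that("trials are discarded iff pre-stretch RMS exceeds 5% of MVC", {
  cfg <- sim_config(n_trials_per_velocity = 1, rng_seed = 21)
  clean <- simulate_subject(cfg)                      # background at 1% MVC
  ft <- filter_trials(clean$trials)
  kept <- reject_trials(ft, clean$mvc_rms)
  expect_true(all(kept$kept))
  expect_true(all(is.na(kept$reject_reason)))
  expect_true(all(kept$max_pre_rms_frac < 0.05))

  # inject a 10%-of-MVC pre-stretch burst -> above the 5% bound
  dirty <- simulate_trial(cfg, 110, contaminated = TRUE, trial_id = "bad")
  res <- reject_trials(filter_trials(dirty), cfg$mvc_rms)
  expect_false(res$kept)
  expect_match(res$reject_reason, "exceeds")
})

test_that("rejection is monotone in pre-stretch EMG amplitude", {
  cfg <- sim_config(n_trials_per_velocity = 1, rng_seed = 22)
  set.seed(22)
  tr <- simulate_trial(cfg, 110)
  base <- reject_trials(filter_trials(tr), cfg$mvc_rms)
  expect_true(base$kept)
  for (scale in c(2, 10, 40)) {
    tr2 <- tr
    tr2$data[[1]] <- dplyr::mutate(
      tr2$data[[1]],
      dplyr::across(dplyr::starts_with("emg_"),
                    ~ ifelse(time_s < tr$stretch_onset_s, .x * scale, .x)))
    res <- reject_trials(filter_trials(tr2), cfg$mvc_rms)
    # scaling up can only move kept -> discarded, never the reverse
    expect_true(res$max_pre_rms_frac >= base$max_pre_rms_frac)
    if (!base$kept) expect_false(res$kept)
  }
  # at 40x the 1%-MVC background (= 40% MVC) the trial must be gone
  tr3 <- tr
  tr3$data[[1]] <- dplyr::mutate(
    tr3$data[[1]],
    dplyr::across(dplyr::starts_with("emg_"),
                  ~ ifelse(time_s < tr$stretch_onset_s, .x * 40, .x)))
  expect_false(reject_trials(filter_trials(tr3), cfg$mvc_rms)$kept)
})

test_that("rejection discards exactly the constructed contaminated trials", {
  cfg <- sim_config(n_trials_per_velocity = 3, rng_seed = 23,
                    contamination_fraction = 0.25)
  subj <- simulate_subject(cfg)
  res <- reject_trials(filter_trials(subj$trials), subj$mvc_rms)
  expect_identical(res$kept, !res$contaminated)
})

test_that("rejection handles empty input and missing MVC references", {
  cfg <- sim_config(n_trials_per_velocity = 1, rng_seed = 24)
  set.seed(24)
  tr <- simulate_trial(cfg, 55)
  empty <- reject_trials(tr[0, ], cfg$mvc_rms)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("kept", "reject_reason") %in% names(empty)))
  expect_error(reject_trials(tr, c(sol = 1)), "mvc_rms")
})
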