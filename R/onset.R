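#' AGLR stretch-reflex EMG onset detection
#'
#' Sequential detection of a variance increase in zero-mean Gaussian EMG by
#' the approximated generalized likelihood-ratio (AGLR) test. The baseline
#' variance \eqn{\sigma_0^2} is taken from a quiescent pre-stretch window.
#' For each candidate endpoint \eqn{k} after the search start, the statistic
#' over the trailing test window of \eqn{L} samples is
#' \deqn{g(k) = (L/2)\,[\hat\sigma_1^2/\sigma_0^2 -
#'   \ln(\hat\sigma_1^2/\sigma_0^2) - 1]}
#' with \eqn{\hat\sigma_1^2} the window maximum-likelihood variance. The
#' alarm fires at the first \eqn{k} with a variance *increase*
#' (\eqn{\hat\sigma_1^2 > \sigma_0^2}) and \eqn{g(k)} above the decision
#' threshold; the onset is then refined as the maximum-likelihood single
#' change point within \eqn{[k - L, k]} (earliest sample on ties).
#'
#' @param emg Filtered EMG trace (numeric).
#' @param fs Sampling rate (Hz).
#' @param stretch_onset_time Stretch onset (s) on the trace's own time axis
#'   (trace assumed to start at `time[1]`, default 0).
#' @param spec An [aglr_spec()].
#' @param time Optional time vector; defaults to a uniform grid from 0.
#' @return A one-row tibble (`onset_s`, `method`, `statistic_peak`,
#'   `no_onset`, `low_snr`): an `OnsetResult`. `onset_s` is `NA` when no
#'   alarm occurs before the end of the trace.
#' @examples
#' cfg <- sim_config(rng_seed = 2)
#' set.seed(2)
#' tr <- simulate_trial(cfg, 110)
#' d <- tr$data[[1]]
#' x <- bandpass_emg(d$emg_sol, cfg$sampling_rate)
#' detect_onset_aglr(x, cfg$sampling_rate, tr$stretch_onset_s)
#' @export
detect_onset_aglr <- function(emg, fs, stretch_onset_time,
                              spec = aglr_spec(), time = NULL) {
  stopifnot(inherits(spec, "aglr_spec"))
  time <- time %||% ((seq_along(emg) - 1) / fs)
  base_idx <- which(time >= stretch_onset_time - spec$baseline_window &
                      time < stretch_onset_time)
  if (length(base_idx) < round(0.2 * fs)) {
    stop("baseline window before stretch onset is too short", call. = FALSE)
  }
  x <- emg - mean(emg[base_idx])
  sigma0_sq <- mean(x[base_idx]^2)
  if (sigma0_sq <= 0) {
    stop("degenerate baseline: zero variance before stretch onset",
         call. = FALSE)
  }

  L <- max(2L, round(spec$test_window * fs))
  start_idx <- which(time >= stretch_onset_time + spec$search_start)[1]
  if (is.na(start_idx)) stop("search start beyond trace end", call. = FALSE)
  n <- length(x)
  cs <- cumsum(c(0, x^2))
  k0 <- max(start_idx + L - 1L, L)
  if (k0 > n) {
    return(onset_result(NA_real_, "aglr", NA_real_, no_onset = TRUE))
  }
  ks <- seq.int(k0, n)
  s1 <- (cs[ks + 1L] - cs[ks - L + 1L]) / L
  r <- s1 / sigma0_sq
  g <- (L / 2) * (r - log(r) - 1)
  alarm <- which(r > 1 & g > spec$decision_threshold)
  if (length(alarm) == 0) {
    return(onset_result(NA_real_, "aglr", max(g[r > 1], 0), no_onset = TRUE))
  }
  k <- ks[alarm[1]]

  # ML refinement: change point j in [k - L + 1, k]; log-likelihood ratio of
  # "variance sigma1 from j onward" vs "all baseline" is
  # n_j/2 * (r_j - ln r_j - 1) with r_j the segment variance ratio. The
  # estimation buffer extends 2L past the alarm to stabilize the segment
  # variance (shrinks worst-case refinement error on gradual-rise bursts).
  kd <- min(n, k + 2L * L)
  js <- seq.int(k - L + 1L, k)
  nj <- kd - js + 1L
  rj <- (cs[kd + 1L] - cs[js]) / nj / sigma0_sq
  score <- ifelse(rj > 1, (nj / 2) * (rj - log(rj) - 1), 0)
  j_hat <- js[which.max(score)]          # which.max takes the earliest tie
  onset_result(time[j_hat], "aglr", g[alarm[1]],
               low_snr = stats::median(r[alarm]) < 4)
}

onset_result <- function(onset_s, method, statistic_peak,
                         no_onset = FALSE, low_snr = FALSE,
                         review = FALSE, note = NA_character_) {
  tibble::tibble(onset_s = onset_s, method = method,
                 statistic_peak = statistic_peak,
                 no_onset = no_onset, low_snr = low_snr,
                 review = review, note = note)
}

#' Sustained-threshold EMG onset detection
#'
#' Surrogate for the manual criterion: the onset is the earliest time after
#' the stretch onset at which the rectified, moving-average-smoothed EMG
#' exceeds the baseline envelope mean by `k_sd` baseline SDs *continuously*
#' for at least `hold` seconds (default two SDs for 100 ms).
#'
#' @inheritParams detect_onset_aglr
#' @param baseline_window Pre-stretch segment (s) for the envelope baseline.
#' @param k_sd Threshold in baseline SDs (default 2).
#' @param hold Minimum supra-threshold duration (s, default 0.1).
#' @param smooth Moving-average width (s) for the rectified envelope
#'   (default 25 ms: short envelopes dip below threshold mid-burst and break
#'   the 100 ms hold, pushing detected onsets deep into the burst).
#' @return A one-row `OnsetResult` tibble (method `"sustained_sd"`).
#' @export
detect_onset_sustained_sd <- function(emg, fs, stretch_onset_time,
                                      baseline_window = 0.5, k_sd = 2,
                                      hold = 0.1, smooth = 0.025,
                                      time = NULL) {
  time <- time %||% ((seq_along(emg) - 1) / fs)
  base_idx <- which(time >= stretch_onset_time - baseline_window &
                      time < stretch_onset_time)
  if (length(base_idx) < round(0.2 * fs)) {
    stop("baseline window before stretch onset is too short", call. = FALSE)
  }
  w <- max(1L, round(smooth * fs))
  env <- as.numeric(stats::filter(abs(emg - mean(emg[base_idx])),
                                  rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  # centered smoothing leaks post-stretch samples into the tail of the
  # baseline; drop one smoothing window from its end for the statistics
  stat_idx <- base_idx[seq_len(max(1L, length(base_idx) - w))]
  mu <- mean(env[stat_idx])
  sdv <- stats::sd(env[stat_idx])
  if (sdv == 0 && k_sd > 0) {
    stop("degenerate baseline: zero envelope variance", call. = FALSE)
  }
  search <- which(time >= stretch_onset_time)
  above <- env[search] > mu + k_sd * sdv
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  ok <- which(runs$values & runs$lengths >= round(hold * fs))
  if (length(ok) == 0) {
    return(onset_result(NA_real_, "sustained_sd", NA_real_, no_onset = TRUE))
  }
  first <- ends[ok[1]] - runs$lengths[ok[1]] + 1L
  onset_result(time[search[first]], "sustained_sd",
               max(env[search]) / max(sdv, .Machine$double.eps))
}

#' Reconcile AGLR and sustained-threshold onsets
#'
#' Automated surrogate for visual inspection of the detector output: the
#' AGLR result is accepted when both detectors agree within
#' `max_disagreement`; otherwise (disagreement, or a missed/extra AGLR
#' detection) the sustained-threshold result is returned and the trial is
#' flagged for review. Every override carries a note so corrections can be
#' logged.
#'
#' @param primary AGLR `OnsetResult` (one-row tibble).
#' @param fallback Sustained-threshold `OnsetResult`.
#' @param max_disagreement Agreement tolerance in s (default 0.02).
#' @return A one-row `OnsetResult` tibble.
#' @export
reconcile_onsets <- function(primary, fallback, max_disagreement = 0.02) {
  if (!primary$no_onset && fallback$no_onset) {
    out <- primary
    out$review <- TRUE
    out$note <- "fallback found no onset; AGLR kept, flagged"
    return(out)
  }
  if (primary$no_onset && !fallback$no_onset) {
    out <- fallback
    out$review <- TRUE
    out$note <- "AGLR no_onset; sustained-SD onset used"
    return(out)
  }
  if (primary$no_onset && fallback$no_onset) {
    out <- primary
    out$note <- "no onset by either method"
    return(out)
  }
  if (abs(primary$onset_s - fallback$onset_s) <= max_disagreement) {
    return(primary)
  }
  out <- fallback
  out$review <- TRUE
  out$note <- sprintf("AGLR/sustained-SD disagreement %.1f ms > %.1f ms; fallback used",
                      1000 * abs(primary$onset_s - fallback$onset_s),
                      1000 * max_disagreement)
  out
}

#' Detect stretch-reflex onsets for every trial and muscle
#'
#' Runs [detect_onset_aglr()] with the [detect_onset_sustained_sd()] fallback
#' and [reconcile_onsets()] on each kept trial and each `emg_*` channel.
#'
#' @param trials Nested trial tibble, already filtered (and typically already
#'   screened with [reject_trials()]; rows with `kept == FALSE` are skipped).
#' @param spec An [aglr_spec()].
#' @param max_disagreement Passed to [reconcile_onsets()].
#' @return A long tibble: one row per trial x muscle with the `OnsetResult`
#'   columns plus `trial_id`, `velocity` and `muscle`.
#' @export
detect_onsets <- function(trials, spec = aglr_spec(), max_disagreement = 0.02) {
  use <- if ("kept" %in% names(trials)) trials[trials$kept, , drop = FALSE] else trials
  if (nrow(use) == 0) {
    return(tibble::tibble(trial_id = character(), velocity = numeric(),
                          muscle = character(), onset_s = numeric(),
                          method = character(), statistic_peak = numeric(),
                          no_onset = logical(), low_snr = logical(),
                          review = logical(), note = character()))
  }
  purrr::map_dfr(seq_len(nrow(use)), function(i) {
    tr <- use$data[[i]]
    fs <- infer_fs(tr$time_s)
    muscles <- sub("^emg_", "", grep("^emg_", names(tr), value = TRUE))
    purrr::map_dfr(muscles, function(m) {
      x <- tr[[paste0("emg_", m)]]
      prim <- detect_onset_aglr(x, fs, use$stretch_onset_s[i], spec,
                                time = tr$time_s)
      fb <- detect_onset_sustained_sd(x, fs, use$stretch_onset_s[i],
                                      baseline_window = spec$baseline_window,
                                      time = tr$time_s)
      res <- reconcile_onsets(prim, fb, max_disagreement)
      dplyr::bind_cols(tibble::tibble(trial_id = use$trial_id[i],
                                      velocity = use$velocity[i],
                                      muscle = m), res)
    })
  })
}

#' Estimate the H-reflex latency from a stimulus-locked trace
#'
#' The latency is the first time inside the search window (after blanking
#' the stimulus artifact) at which the absolute deviation of the EMG from
#' the pre-stimulus baseline mean exceeds `k_sd` baseline SDs sustained for
#' at least 2 ms — the initial deflection of the H-wave.
#'
#' @param trace Tibble with `time_s` (s, stimulus at 0) and `emg` columns,
#'   e.g. from [simulate_hreflex()].
#' @param artifact_blank Time (s) after the stimulus blanked before searching.
#' @param search_window Two-element window (s) in which the H-wave is
#'   expected; default `c(0.015, 0.050)`.
#' @param k_sd Detection threshold in baseline SDs.
#' @param min_sustained Minimum supra-threshold duration (s).
#' @return Latency in seconds.
#' @examples
#' estimate_hreflex_latency(simulate_hreflex(0.028, noise_sd = 0.005))
#' @export
estimate_hreflex_latency <- function(trace, artifact_blank = 0.005,
                                     search_window = c(0.015, 0.050),
                                     k_sd = 3, min_sustained = 0.002) {
  stopifnot(all(c("time_s", "emg") %in% names(trace)),
            length(search_window) == 2, search_window[1] < search_window[2])
  fs <- infer_fs(trace$time_s)
  if (search_window[2] > max(trace$time_s)) {
    stop("search window extends beyond the trace", call. = FALSE)
  }
  base <- trace$emg[trace$time_s < 0]
  if (length(base) < 10) stop("no pre-stimulus baseline in trace", call. = FALSE)
  mu <- mean(base)
  sdv <- stats::sd(base)
  lo <- max(search_window[1], artifact_blank)
  idx <- which(trace$time_s >= lo & trace$time_s <= search_window[2])
  dev <- abs(trace$emg[idx] - mu)
  thr <- if (sdv > 0) k_sd * sdv else .Machine$double.eps
  above <- dev > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  ok <- which(runs$values & runs$lengths >= max(2L, round(min_sustained * fs)))
  if (length(ok) == 0) {
    stop("no H-reflex deflection found in the search window: latency unmeasurable",
         call. = FALSE)
  }
  first <- ends[ok[1]] - runs$lengths[ok[1]] + 1L
  trace$time_s[idx[first]]
}
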