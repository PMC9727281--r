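#' Joint angle at an arbitrary time
#'
#' Linear interpolation of a trial's angle trace. At 2 kHz and velocities up
#' to 291 deg/s the inter-sample angular step is at most ~0.15 deg, so
#' interpolation error is negligible against reported SRT variability.
#'
#' @param trace Trial trace tibble with `time_s` and `angle_deg` columns
#'   (a `data` element of a nested trial tibble).
#' @param t Time(s) in s; must lie within the trace's time range.
#' @return Angle(s) in degrees of plantarflexion.
#' @export
angle_at_time <- function(trace, t) {
  rng <- range(trace$time_s)
  if (any(t < rng[1] - 1e-12 | t > rng[2] + 1e-12)) {
    stop("time outside the trial's recorded range", call. = FALSE)
  }
  stats::approx(trace$time_s, trace$angle_deg, xout = t, rule = 2)$y
}

#' Per-trial stretch reflex threshold, with and without latency correction
#'
#' The original SRT is the joint angle at the stretch-reflex EMG onset time.
#' The latency-corrected SRT is the joint angle at the EMG onset time
#' *minus* the individual reflex latency — the angle at which the reflex was
#' mechanically initiated at the muscle spindles. In the decreasing
#' plantarflexion convention the corrected SRT is therefore never smaller
#' than the uncorrected one.
#'
#' @param trace Trial trace tibble (`time_s`, `angle_deg`).
#' @param onset_s Detected EMG onset time (s).
#' @param latency Individual reflex latency (s), typically the subject's
#'   H-reflex latency for that muscle; must be >= 0.
#' @return A one-row tibble: `srt`, `srt_corrected` (deg), `onset_s`,
#'   `latency_used`.
#' @examples
#' cfg <- sim_config(rng_seed = 3)
#' set.seed(3)
#' tr <- simulate_trial(cfg, 55)
#' compute_srt(tr$data[[1]], tr$true_emg_onset_sol_s, 0.028)
#' @export
compute_srt <- function(trace, onset_s, latency) {
  stopifnot(length(onset_s) == 1, !is.na(onset_s), latency >= 0)
  if (onset_s - latency < min(trace$time_s)) {
    stop("onset minus latency falls before the start of the recording",
         call. = FALSE)
  }
  tibble::tibble(
    srt = angle_at_time(trace, onset_s),
    srt_corrected = angle_at_time(trace, onset_s - latency),
    onset_s = onset_s,
    latency_used = latency
  )
}

#' Per-trial SRT table for a subject
#'
#' Joins detected onsets with trial traces and the subject's per-muscle
#' reflex latencies.
#'
#' @param trials Nested trial tibble.
#' @param onsets Onset table from [detect_onsets()] (rows with `no_onset`
#'   are dropped).
#' @param h_latency_s Named per-muscle latency vector (s).
#' @return Tibble: `trial_id`, `muscle`, `velocity`, `srt`, `srt_corrected`,
#'   `onset_s`, `latency_used`, `method`, `review`.
#' @export
compute_srt_table <- function(trials, onsets, h_latency_s) {
  ok <- onsets[!onsets$no_onset, , drop = FALSE]
  if (nrow(ok) == 0) {
    return(tibble::tibble(trial_id = character(), muscle = character(),
                          velocity = numeric(), srt = numeric(),
                          srt_corrected = numeric(), onset_s = numeric(),
                          latency_used = numeric(), method = character(),
                          review = logical()))
  }
  purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    row <- ok[i, ]
    tr <- trials$data[[match(row$trial_id, trials$trial_id)]]
    est <- compute_srt(tr, row$onset_s, h_latency_s[[row$muscle]])
    dplyr::bind_cols(
      tibble::tibble(trial_id = row$trial_id, muscle = row$muscle,
                     velocity = row$velocity),
      est,
      tibble::tibble(method = row$method, review = row$review)
    )
  })
}

#' Angular error accrued during the reflex latency
#'
#' At constant stretch velocity the EMG onset lags the mechanical reflex
#' onset by the reflex latency, so the uncorrected SRT is displaced by
#' `latency * velocity` degrees — e.g. 1.5 deg at 50 deg/s but 9 deg at
#' 300 deg/s for a 30 ms latency.
#'
#' @param latency Reflex latency (s), >= 0.
#' @param velocity Stretch velocity (deg/s), >= 0. Vectorized.
#' @return Angular displacement in degrees.
#' @examples
#' latency_error(0.030, c(50, 300))
#' @export
latency_error <- function(latency, velocity) {
  stopifnot(all(latency >= 0), all(velocity >= 0))
  latency * velocity
}

#' Bound on the H-reflex pathway approximation error
#'
#' The H-reflex is evoked at the popliteal fossa and bypasses the muscle
#' spindle, so it underestimates the stretch-reflex latency by at most a
#' fraction of the Ia arc pathway (anatomically at most ~15%). This returns
#' the corresponding worst-case timing error and the angular error it causes
#' at the fastest stretch velocity.
#'
#' @param mean_latency Mean measured H-reflex latency (s).
#' @param fraction Maximal unmeasured fraction of the pathway (0-1).
#' @param max_velocity Fastest stretch velocity (deg/s).
#' @return Named numeric vector: `time_s`, `angle_deg`.
#' @examples
#' pathway_error_bound(0.028, 0.15, 291)
#' @export
pathway_error_bound <- function(mean_latency, fraction, max_velocity) {
  stopifnot(fraction > 0 || fraction == 0, fraction < 1, mean_latency >= 0)
  dt <- fraction * mean_latency
  c(time_s = dt, angle_deg = dt * max_velocity)
}

#' Per-velocity median SRTs for one subject
#'
#' Medians (midpoint convention for even counts, i.e. `stats::median`) of
#' `srt` and `srt_corrected` per muscle and velocity.
#'
#' @param estimates SRT table from [compute_srt_table()].
#' @param required_velocities Optional velocities that must be present; a
#'   velocity with no surviving trial appears with `NA` medians and
#'   `n = 0` so downstream exclusion can act on it.
#' @return Tibble: `muscle`, `velocity`, `n`, `srt_median`,
#'   `srt_corrected_median`.
#' @export
aggregate_medians <- function(estimates, required_velocities = NULL) {
  out <- estimates |>
    dplyr::group_by(.data$muscle, .data$velocity) |>
    dplyr::summarise(n = dplyr::n(),
                     srt_median = stats::median(.data$srt),
                     srt_corrected_median = stats::median(.data$srt_corrected),
                     .groups = "drop")
  if (!is.null(required_velocities)) {
    grid <- tidyr::expand_grid(muscle = unique(c(estimates$muscle, out$muscle)),
                               velocity = as.numeric(required_velocities))
    out <- dplyr::left_join(grid, out, by = c("muscle", "velocity")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  dplyr::arrange(out, .data$muscle, .data$velocity)
}

#' Velocity-SRT regression and tonic stretch reflex threshold
#'
#' Ordinary least squares of the per-velocity median SRT (y) on stretch
#' velocity (x). The tonic stretch reflex threshold (TSRT) is the
#' y-intercept — the extrapolated threshold angle at zero velocity. The
#' slope classifies velocity dependence: `near_zero` when |slope| < 0.01
#' deg per (deg/s) (over a 55-291 deg/s range that is at most a 2.36 deg
#' change, below typical within-subject SRT variability), otherwise
#' `positive` or `negative` by sign.
#'
#' The regression is refused unless *all* `required_velocities` have a
#' median — subjects without SRTs at every velocity are excluded rather
#' than fitted on fewer points.
#'
#' @param medians Tibble with `velocity` and the value column (for one
#'   muscle/method), e.g. a filtered output of [aggregate_medians()].
#' @param value Name of the column holding the per-velocity medians
#'   (default `"srt_median"`).
#' @param required_velocities Velocities that must all be present (default:
#'   those in `medians`); at least 3.
#' @param near_zero_bound Modulus bound defining a near-zero slope.
#' @return An object of class `velocity_regression` with elements `slope`
#'   (deg per deg/s), `intercept_tsrt` (deg), `r_squared`, `n_velocities`,
#'   `dependence_class`, `zero_variance` flag, `points` and `model` (the
#'   `lm` fit). Has [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' med <- tibble::tibble(velocity = c(55, 110, 210, 291),
#'                       srt_median = 19 - 0.028 * c(55, 110, 210, 291))
#' glance(fit_velocity_regression(med))
#' @export
fit_velocity_regression <- function(medians, value = "srt_median",
                                    required_velocities = NULL,
                                    near_zero_bound = 0.01) {
  stopifnot(value %in% names(medians), "velocity" %in% names(medians))
  req <- sort(as.numeric(required_velocities %||% unique(medians$velocity)))
  if (length(req) < 3) {
    stop("need at least 3 velocities for the velocity-SRT regression",
         call. = FALSE)
  }
  pts <- medians[!is.na(medians[[value]]), c("velocity", value)]
  missing_v <- setdiff(req, pts$velocity)
  if (length(missing_v) > 0) {
    stop("subject excluded: no SRT median at velocity ",
         paste(missing_v, collapse = ", "), " deg/s (all required ",
         "velocities must be quantified)", call. = FALSE)
  }
  pts <- pts[pts$velocity %in% req, ]
  names(pts) <- c("velocity", "srt")
  fit <- stats::lm(srt ~ velocity, data = pts)
  slope <- unname(stats::coef(fit)[2])
  zero_var <- stats::var(pts$srt) == 0
  # direct R^2 (summary.lm warns on numerically perfect fits)
  tss <- sum((pts$srt - mean(pts$srt))^2)
  r2 <- if (zero_var) 0 else max(0, min(1, 1 - sum(stats::resid(fit)^2) / tss))
  cls <- if (abs(slope) < near_zero_bound) "near_zero"
         else if (slope > 0) "positive" else "negative"
  structure(
    list(slope = slope,
         intercept_tsrt = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_velocities = nrow(pts),
         dependence_class = cls,
         zero_variance = zero_var,
         near_zero_bound = near_zero_bound,
         points = tibble::as_tibble(pts),
         model = fit),
    class = "velocity_regression"
  )
}

#' @export
print.velocity_regression <- function(x, ...) {
  cat(sprintf("<velocity_regression> %d velocities\n", x$n_velocities))
  cat(sprintf("  slope %+.4f deg/(deg/s) [%s], TSRT %.2f deg, R^2 %.3f%s\n",
              x$slope, x$dependence_class, x$intercept_tsrt, x$r_squared,
              if (x$zero_variance) " (zero-variance y)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_velocity_regression
#' @param x,object A `velocity_regression`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.velocity_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_velocity_regression
#' @exportS3Method generics::glance
glance.velocity_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept_tsrt = x$intercept_tsrt,
                 r_squared = x$r_squared, n_velocities = x$n_velocities,
                 dependence_class = x$dependence_class,
                 zero_variance = x$zero_variance)
}

#' Fit both methods' velocity regressions for every muscle
#'
#' Convenience wrapper running [fit_velocity_regression()] for the original
#' (`srt_median`) and latency-corrected (`srt_corrected_median`) columns of
#' an [aggregate_medians()] table, per muscle.
#'
#' @param medians Output of [aggregate_medians()].
#' @param required_velocities Velocities every fit must cover.
#' @inheritParams fit_velocity_regression
#' @return Tibble with one row per muscle x method: the [glance()] columns
#'   plus a `fit` list-column of `velocity_regression` objects.
#' @export
fit_velocity_regressions <- function(medians, required_velocities = NULL,
                                     near_zero_bound = 0.01) {
  grid <- tidyr::expand_grid(muscle = unique(medians$muscle),
                             method = c("original", "corrected"))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    m <- grid$muscle[i]
    col <- if (grid$method[i] == "original") "srt_median" else "srt_corrected_median"
    fit <- fit_velocity_regression(medians[medians$muscle == m, ],
                                   value = col,
                                   required_velocities = required_velocities,
                                   near_zero_bound = near_zero_bound)
    dplyr::bind_cols(grid[i, ], glance(fit), tibble::tibble(fit = list(fit)))
  })
}
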