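#' Simulation configuration for the synthetic dynamometer + EMG generator
#'
#' Bundles every parameter of the synthetic passive-stretch study: the motor
#' trajectory (constant-acceleration ramp from `start_angle` to `end_angle`
#' degrees of plantarflexion at each nominal velocity), the reflex model
#' (a true threshold angle crossed by the commanded trajectory, an EMG burst
#' appearing one reflex latency later), and the surface-EMG noise model.
#'
#' Angle convention: degrees of plantarflexion, positive, *decreasing* during
#' dorsiflexion, so a stretch runs 20 -> 0 and "earlier in the stretch" means
#' a *larger* angle.
#'
#' @param sampling_rate Sampling rate in Hz for angle and EMG.
#' @param velocities Nominal stretch velocities in deg/s.
#' @param n_trials_per_velocity Stretch repetitions per velocity.
#' @param start_angle,end_angle Plantarflexion angles (deg) at stretch start
#'   and end; `start_angle > end_angle`.
#' @param accel_duration Duration (s) of the constant-acceleration phase
#'   before the nominal velocity is reached.
#' @param true_threshold_angle Joint angle (deg) at which the stretch reflex
#'   is mechanically initiated, at zero velocity.
#' @param threshold_velocity_slope Built-in velocity dependence of the true
#'   threshold, in deg per (deg/s); 0 gives a velocity-independent reflex.
#' @param latency Reflex latency (s) per muscle: time from the mechanical
#'   reflex onset at the spindles to its appearance in the EMG. Scalar or a
#'   named vector with entries `sol` and `mg`.
#' @param background_sd Standard deviation of the band-limited background EMG
#'   (amplitude units; `mvc_rms` of 1 makes this a fraction of MVC RMS).
#' @param burst_gain Reflex burst size: the EMG standard deviation rises to
#'   `burst_gain * background_sd` during the burst. Must exceed 1.
#' @param burst_rise_time Linear rise time (s) of the burst envelope.
#' @param mvc_rms EMG RMS (amplitude units) of the maximal voluntary
#'   contraction reference, per muscle (scalar or named vector).
#' @param pre_stretch_duration Quiescent recording (s) before stretch onset;
#'   must cover the 0.5 s rejection/baseline window.
#' @param post_hold_duration Recording (s) kept after the ramp ends, so the
#'   reflex burst is sustained well past onset.
#' @param contamination_fraction Proportion of trials carrying a pre-stretch
#'   activation burst that should trip the background-activity rejection.
#' @param contamination_level Pre-stretch contamination RMS as a fraction of
#'   MVC RMS (default 0.10, i.e. twice the 5% rejection bound).
#' @param h_latency_mean,h_latency_sd,h_latency_range Distribution (s) from
#'   which per-subject, per-muscle H-reflex latencies are drawn (truncated
#'   normal).
#' @param rng_seed Integer seed; identical configuration + seed reproduces
#'   the dataset bit for bit.
#'
#' @return An object of class `srt_sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(velocities = c(55, 110), n_trials_per_velocity = 2)
#' cfg$sampling_rate
#' @export
sim_config <- function(sampling_rate = 2000,
                       velocities = c(55, 110, 210, 291),
                       n_trials_per_velocity = 10,
                       start_angle = 20,
                       end_angle = 0,
                       accel_duration = 0.030,
                       true_threshold_angle = 19,
                       threshold_velocity_slope = 0,
                       latency = c(sol = 0.028, mg = 0.028),
                       background_sd = 0.01,
                       burst_gain = 5,
                       burst_rise_time = 0.010,
                       mvc_rms = c(sol = 1, mg = 1),
                       pre_stretch_duration = 0.6,
                       post_hold_duration = 0.4,
                       contamination_fraction = 0,
                       contamination_level = 0.10,
                       h_latency_mean = 0.028,
                       h_latency_sd = 0.003,
                       h_latency_range = c(0.023, 0.035),
                       rng_seed = NULL) {
  latency <- expand_muscles(latency, "latency")
  mvc_rms <- expand_muscles(mvc_rms, "mvc_rms")

  stopifnot(
    sampling_rate > 0,
    length(velocities) >= 1, all(velocities > 0),
    n_trials_per_velocity >= 0,
    start_angle > end_angle,
    accel_duration > 0,
    all(latency >= 0), all(latency <= 0.050),
    background_sd >= 0,
    burst_gain > 1,
    burst_rise_time > 0,
    all(mvc_rms > 0),
    pre_stretch_duration >= 0.5,
    contamination_fraction >= 0, contamination_fraction <= 1,
    contamination_level > 0
  )
  if (accel_duration < 0.02 || accel_duration > 0.04) {
    warning("accel_duration outside the 20-40 ms actuator range", call. = FALSE)
  }

  cfg <- list(
    sampling_rate = sampling_rate,
    velocities = as.numeric(velocities),
    n_trials_per_velocity = as.integer(n_trials_per_velocity),
    start_angle = start_angle,
    end_angle = end_angle,
    accel_duration = accel_duration,
    true_threshold_angle = true_threshold_angle,
    threshold_velocity_slope = threshold_velocity_slope,
    latency = latency,
    background_sd = background_sd,
    burst_gain = burst_gain,
    burst_rise_time = burst_rise_time,
    mvc_rms = mvc_rms,
    pre_stretch_duration = pre_stretch_duration,
    post_hold_duration = post_hold_duration,
    contamination_fraction = contamination_fraction,
    contamination_level = contamination_level,
    h_latency_mean = h_latency_mean,
    h_latency_sd = h_latency_sd,
    h_latency_range = h_latency_range,
    rng_seed = rng_seed
  )
  # the reflex must fire strictly inside the stretched range at every velocity
  thr <- true_threshold_angle + threshold_velocity_slope * cfg$velocities
  if (any(thr >= start_angle | thr <= end_angle)) {
    stop("true threshold angle falls outside (end_angle, start_angle) at ",
         "velocity ", cfg$velocities[which(thr >= start_angle | thr <= end_angle)[1]],
         " deg/s: the reflex would never fire within the stretch", call. = FALSE)
  }
  structure(cfg, class = "srt_sim_config")
}

expand_muscles <- function(x, what, muscles = c("sol", "mg")) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- stats::setNames(rep(x, length(muscles)), muscles)
    else stop(what, " must be a scalar or a named vector", call. = FALSE)
  }
  if (!all(muscles %in% names(x))) {
    stop(what, " must name all muscles: ", paste(muscles, collapse = ", "),
         call. = FALSE)
  }
  x[muscles]
}

#' @export
print.srt_sim_config <- function(x, ...) {
  cat("<srt_sim_config>\n")
  cat(sprintf("  fs %g Hz | velocities %s deg/s x %d trials\n",
              x$sampling_rate, paste(x$velocities, collapse = "/"),
              x$n_trials_per_velocity))
  cat(sprintf("  stretch %g -> %g deg, accel %g ms\n",
              x$start_angle, x$end_angle, 1000 * x$accel_duration))
  cat(sprintf("  threshold %g deg (slope %g deg per deg/s), latency sol %g / mg %g ms\n",
              x$true_threshold_angle, x$threshold_velocity_slope,
              1000 * x$latency[["sol"]], 1000 * x$latency[["mg"]]))
  cat(sprintf("  background SD %g, burst gain %g, contamination %g%%\n",
              x$background_sd, x$burst_gain, 100 * x$contamination_fraction))
  invisible(x)
}

#' EMG band-pass filter specification
#'
#' @param low_cut,high_cut Corner frequencies in Hz (defaults 20 and 195, the
#'   off-line analysis band).
#' @param order Butterworth order of the underlying one-pass design.
#' @param zero_phase Apply forward-backward so the filter adds no delay;
#'   mandatory when onset *timing* is the measurand.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 20, high_cut = 195, order = 4,
                        zero_phase = TRUE) {
  stopifnot(low_cut > 0, high_cut > low_cut, order >= 1)
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Background-activation trial rejection specification
#'
#' A trial is discarded when, for any muscle, the sliding-window EMG RMS in
#' the pre-stretch interval exceeds `mvc_fraction` of that muscle's MVC RMS.
#'
#' @param rms_window RMS window length in s (default 0.2).
#' @param pre_window Pre-stretch interval inspected, in s (default 0.5).
#' @param mvc_fraction Rejection bound as a proportion of MVC RMS
#'   (default 0.05).
#' @return A `rejection_spec` list.
#' @export
rejection_spec <- function(rms_window = 0.2, pre_window = 0.5,
                           mvc_fraction = 0.05) {
  stopifnot(rms_window > 0, pre_window >= rms_window,
            mvc_fraction > 0, mvc_fraction < 1)
  structure(list(rms_window = rms_window, pre_window = pre_window,
                 mvc_fraction = mvc_fraction), class = "rejection_spec")
}

#' AGLR onset-detector specification
#'
#' Parameters of the approximated generalized likelihood-ratio test for a
#' variance increase in zero-mean Gaussian EMG. The decision threshold is
#' calibrated so that the false-alarm rate on pure band-limited background
#' traces stays below 1% (the calibration is part of the test suite).
#'
#' @param test_window Sliding test window length in s.
#' @param decision_threshold Alarm threshold on the log-likelihood statistic.
#' @param baseline_window Pre-stretch segment (s) used for the baseline
#'   variance; at least 0.2 s.
#' @param search_start Offset (s) after stretch onset at which the scan
#'   starts.
#' @return An `aglr_spec` list.
#' @export
aglr_spec <- function(test_window = 0.025, decision_threshold = 45,
                      baseline_window = 0.5, search_start = 0) {
  stopifnot(test_window > 0, decision_threshold > 0, baseline_window >= 0.2,
            search_start >= 0)
  structure(list(test_window = test_window,
                 decision_threshold = decision_threshold,
                 baseline_window = baseline_window,
                 search_start = search_start), class = "aglr_spec")
}
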