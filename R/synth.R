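#' Commanded angle trajectory of a passive stretch
#'
#' Closed-form dynamometer trajectory: a plateau at `start_angle`, a
#' constant-acceleration phase of duration `accel_duration` reaching the
#' nominal velocity, a constant-velocity ramp, and a plateau at `end_angle`.
#'
#' @param t Time(s) in seconds (any numeric vector).
#' @param velocity Nominal stretch velocity in deg/s (positive).
#' @param cfg A [sim_config()].
#' @param stretch_onset Time (s) at which the ramp starts.
#' @return Angle(s) in degrees of plantarflexion.
#' @keywords internal
commanded_angle <- function(t, velocity, cfg, stretch_onset = cfg$pre_stretch_duration) {
  a <- velocity / cfg$accel_duration          # angular acceleration, deg/s^2
  range <- cfg$start_angle - cfg$end_angle
  accel_drop <- 0.5 * velocity * cfg$accel_duration
  if (accel_drop >= range) {
    stop("acceleration phase alone exceeds the range of motion", call. = FALSE)
  }
  t_const_end <- cfg$accel_duration + (range - accel_drop) / velocity
  tau <- t - stretch_onset
  drop <- numeric(length(t))
  in_accel <- tau > 0 & tau <= cfg$accel_duration
  in_const <- tau > cfg$accel_duration & tau <= t_const_end
  after <- tau > t_const_end
  drop[in_accel] <- 0.5 * a * tau[in_accel]^2
  drop[in_const] <- accel_drop + velocity * (tau[in_const] - cfg$accel_duration)
  drop[after] <- range
  cfg$start_angle - drop
}

#' Time at which the commanded trajectory crosses the true threshold angle
#'
#' Defined on the noiseless commanded trajectory so the ground truth does not
#' depend on measurement noise. Returned relative to trial time 0.
#'
#' @inheritParams commanded_angle
#' @return Crossing time in s.
#' @keywords internal
threshold_crossing_time <- function(velocity, cfg,
                                    stretch_onset = cfg$pre_stretch_duration) {
  thr <- cfg$true_threshold_angle + cfg$threshold_velocity_slope * velocity
  drop_needed <- cfg$start_angle - thr
  if (drop_needed <= 0 || thr <= cfg$end_angle) {
    stop("true threshold angle outside the stretched range at ",
         velocity, " deg/s", call. = FALSE)
  }
  accel_drop <- 0.5 * velocity * cfg$accel_duration
  tau <- if (drop_needed <= accel_drop) {
    sqrt(2 * drop_needed * cfg$accel_duration / velocity)
  } else {
    cfg$accel_duration + (drop_needed - accel_drop) / velocity
  }
  stretch_onset + tau
}

# White Gaussian noise band-passed to the surface-EMG support (20-450 Hz)
# and rescaled to unit empirical SD; the analysis band (20-195 Hz) then has
# something realistic to remove.
band_limited_noise <- function(n, fs, low = 20, high = 450) {
  high <- min(high, 0.45 * fs)
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate one synthetic passive-stretch trial
#'
#' Produces one dorsiflexion trial: the commanded angle trajectory plus
#' band-limited Gaussian background EMG for both muscles, with a
#' variance-increase reflex burst starting one reflex latency after the
#' commanded trajectory crosses the true threshold angle. The burst is a
#' multiplicative envelope rising linearly over `burst_rise_time` to
#' `burst_gain` times the background SD and sustained to the end of the
#' trial, so sustained-threshold criteria can fire.
#'
#' @param cfg A [sim_config()].
#' @param velocity Nominal velocity (deg/s); must be one of `cfg$velocities`.
#' @param contaminated Inject a pre-stretch activation burst (at
#'   `cfg$contamination_level` of MVC RMS) into one muscle, so the trial
#'   should be discarded by [reject_trials()].
#' @param trial_id Identifier stored with the trial.
#' @return A one-row tibble with columns `trial_id`, `velocity`,
#'   `stretch_onset_s`, `contaminated`, truth columns `true_sr_onset_s` and
#'   `true_emg_onset_s` (per-muscle onsets are `true_sr_onset_s + latency`),
#'   and a `data` list-column holding the trace tibble
#'   (`time_s`, `angle_deg`, `emg_sol`, `emg_mg`).
#' @examples
#' cfg <- sim_config(rng_seed = 1)
#' set.seed(1)
#' tr <- simulate_trial(cfg, velocity = 110)
#' tr$data[[1]]
#' @export
simulate_trial <- function(cfg, velocity, contaminated = FALSE,
                           trial_id = "t001") {
  stopifnot(inherits(cfg, "srt_sim_config"))
  if (!velocity %in% cfg$velocities) {
    stop("velocity ", velocity, " is not in cfg$velocities", call. = FALSE)
  }
  fs <- cfg$sampling_rate
  onset <- cfg$pre_stretch_duration
  range <- cfg$start_angle - cfg$end_angle
  accel_drop <- 0.5 * velocity * cfg$accel_duration
  ramp_dur <- cfg$accel_duration + (range - accel_drop) / velocity
  n <- ceiling((onset + ramp_dur + cfg$post_hold_duration) * fs) + 1
  time_s <- (seq_len(n) - 1) / fs

  angle <- commanded_angle(time_s, velocity, cfg, onset)
  t_sr <- threshold_crossing_time(velocity, cfg, onset)

  emg <- list()
  contaminated_muscle <- if (contaminated) sample(c("sol", "mg"), 1) else NA_character_
  for (m in c("sol", "mg")) {
    t_emg <- t_sr + cfg$latency[[m]]
    env <- rep(1, n)
    rising <- time_s >= t_emg
    env[rising] <- 1 + (cfg$burst_gain - 1) *
      pmin(1, (time_s[rising] - t_emg) / cfg$burst_rise_time)
    if (identical(m, contaminated_muscle)) {
      # activation burst inside the 500 ms rejection window, scaled so the
      # pre-filter RMS reaches contamination_level * MVC RMS
      w <- time_s >= onset - 0.45 & time_s <= onset - 0.15
      env[w] <- cfg$contamination_level * cfg$mvc_rms[[m]] / cfg$background_sd
    }
    emg[[paste0("emg_", m)]] <- cfg$background_sd * env * band_limited_noise(n, fs)
  }

  trace <- tibble::tibble(time_s = time_s, angle_deg = angle,
                          emg_sol = emg$emg_sol, emg_mg = emg$emg_mg)
  tibble::tibble(
    trial_id = trial_id,
    velocity = velocity,
    stretch_onset_s = onset,
    contaminated = contaminated,
    contaminated_muscle = contaminated_muscle,
    true_sr_onset_s = t_sr,
    true_emg_onset_sol_s = t_sr + cfg$latency[["sol"]],
    true_emg_onset_mg_s = t_sr + cfg$latency[["mg"]],
    data = list(trace)
  )
}

#' Generate a synthetic subject
#'
#' Ten stretches per velocity (configurable) in pseudo-randomized order, a
#' per-muscle H-reflex latency drawn once from a truncated normal
#' (mean 28 ms, SD 3 ms, range 23-35 ms by default) and used in every trial,
#' and `contamination_fraction` of trials carrying pre-stretch activation.
#'
#' @param cfg A [sim_config()]. If `cfg$rng_seed` is set the subject is
#'   reproducible bit for bit.
#' @param subject_id Identifier.
#' @return An `srt_subject`: a list with `trials` (nested tibble, one row per
#'   trial), `h_latency_s` (named per-muscle vector), `mvc_rms`, `config`
#'   and `subject_id`.
#' @examples
#' subj <- simulate_subject(sim_config(n_trials_per_velocity = 2, rng_seed = 7))
#' nrow(subj$trials)
#' @export
simulate_subject <- function(cfg, subject_id = "s01") {
  stopifnot(inherits(cfg, "srt_sim_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)

  h_lat <- vapply(c("sol", "mg"), function(m) {
    rtruncnorm1(cfg$h_latency_mean, cfg$h_latency_sd, cfg$h_latency_range)
  }, numeric(1))
  # each muscle's EMG onset lags the mechanical reflex onset by that
  # subject's own H-reflex latency
  cfg$latency <- h_lat

  plan <- tibble::tibble(
    velocity = rep(cfg$velocities, each = cfg$n_trials_per_velocity)
  )
  n_tr <- nrow(plan)
  if (n_tr == 0) {
    trials <- simulate_trial(cfg, cfg$velocities[1])[0, ]
  } else {
    plan <- plan[sample.int(n_tr), , drop = FALSE]   # pseudo-randomized order
    n_cont <- round(cfg$contamination_fraction * n_tr)
    contam <- rep(FALSE, n_tr)
    if (n_cont > 0) contam[sample.int(n_tr, n_cont)] <- TRUE
    trials <- purrr::map_dfr(seq_len(n_tr), function(i) {
      simulate_trial(cfg, plan$velocity[i], contaminated = contam[i],
                     trial_id = sprintf("%s_t%03d", subject_id, i))
    })
  }
  structure(
    list(subject_id = subject_id, trials = trials, h_latency_s = h_lat,
         mvc_rms = cfg$mvc_rms, config = cfg),
    class = "srt_subject"
  )
}

rtruncnorm1 <- function(mean, sd, range) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  mean
}

#' @export
print.srt_subject <- function(x, ...) {
  cat(sprintf("<srt_subject %s> %d trials (%s deg/s), H-reflex latency sol %.1f / mg %.1f ms\n",
              x$subject_id, nrow(x$trials),
              paste(x$config$velocities, collapse = "/"),
              1000 * x$h_latency_s[["sol"]], 1000 * x$h_latency_s[["mg"]]))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param cfg A [sim_config()]; per-subject seeds are derived from
#'   `cfg$rng_seed` so the cohort is reproducible.
#' @param n_subjects Number of subjects.
#' @return A list of [simulate_subject()] objects.
#' @export
simulate_cohort <- function(cfg, n_subjects) {
  stopifnot(n_subjects >= 0)
  base_seed <- if (is.null(cfg$rng_seed)) NULL else cfg$rng_seed
  purrr::map(seq_len(n_subjects), function(i) {
    cfg_i <- cfg
    if (!is.null(base_seed)) cfg_i$rng_seed <- (base_seed + 7919L * i) %% .Machine$integer.max
    simulate_subject(cfg_i, subject_id = sprintf("s%02d", i))
  })
}

#' Generate a stimulus-locked H-reflex trace
#'
#' Emulates a single tibial-nerve stimulation sweep: baseline noise before
#' the stimulus, a large stimulus artifact at time 0, an optional biphasic
#' M-wave near 7 ms, and a biphasic H-wave whose first deflection begins at
#' `latency`. The trace is noise-only between the end of the artifact and
#' the H-wave (apart from the M-wave), which is what latency estimation
#' relies on.
#'
#' @param latency True H-reflex latency in s, within \[0.015, 0.050\].
#' @param fs Sampling rate (Hz).
#' @param noise_sd Baseline noise SD (amplitude units); 0 gives a noiseless
#'   trace.
#' @param h_amplitude,m_amplitude Peak amplitudes of the H- and M-waves.
#' @param pre,post Trace extent (s) before and after the stimulus.
#' @return A tibble `time_s`, `emg` with attribute `h_latency` (the truth).
#' @examples
#' tr <- simulate_hreflex(0.028, noise_sd = 0)
#' attr(tr, "h_latency")
#' @export
simulate_hreflex <- function(latency, fs = 2000, noise_sd = 0.01,
                             h_amplitude = 0.5, m_amplitude = 0.3,
                             pre = 0.05, post = 0.06) {
  stopifnot(latency >= 0.015, latency <= 0.050)
  n <- ceiling((pre + post) * fs) + 1
  time_s <- (seq_len(n) - 1) / fs - pre
  emg <- if (noise_sd > 0) noise_sd * band_limited_noise(n, fs) else numeric(n)

  biphasic <- function(t0, dur, amp) {
    w <- time_s >= t0 & time_s < t0 + dur
    out <- numeric(n)
    out[w] <- amp * sin(2 * pi * (time_s[w] - t0) / dur)
    out
  }
  artifact <- numeric(n)
  aw <- time_s >= 0 & time_s < 0.002
  artifact[aw] <- 3 * h_amplitude * exp(-time_s[aw] / 0.0005)
  emg <- emg + artifact +
    biphasic(0.007, 0.006, m_amplitude) +       # M-wave, ends well before 15 ms
    biphasic(latency, 0.010, h_amplitude)       # H-wave first deflection at latency

  out <- tibble::tibble(time_s = time_s, emg = emg)
  attr(out, "h_latency") <- latency
  out
}

#' Simulate per-subject median SRT matrices at the measurement level
#'
#' Cohort-scale generator operating on SRT values directly (commanded
#' kinematics + onset-timing jitter) rather than raw EMG traces, for
#' validating the group-level statistics on many replicate cohorts. Each
#' subject gets an individual true threshold angle and reflex latency; each
#' trial's detected EMG onset is the true onset plus Gaussian timing jitter
#' whose SD matches the accuracy of the EMG onset detector on default-noise
#' traces. Per-velocity medians of both SRT methods are returned as
#' complete subjects-by-velocities matrices.
#'
#' @param n_subjects Cohort size (default 12, the per-muscle analyzable
#'   sample of a typical single-muscle cohort).
#' @param cfg A [sim_config()] supplying kinematics, velocities, trial count
#'   and the H-reflex latency distribution.
#' @param theta_mean,theta_sd Between-subject distribution (deg) of the true
#'   threshold angle (truncated to fall inside the stretched range at every
#'   velocity).
#' @param onset_jitter_sd SD (s) of the onset-timing error (default 4 ms).
#' @return List with matrices `original` and `corrected` (rows subjects,
#'   columns velocities), and vectors `theta` and `latency_s`.
#' @export
simulate_srt_cohort <- function(n_subjects = 12, cfg = sim_config(),
                                theta_mean = 19, theta_sd = 2,
                                onset_jitter_sd = 0.004) {
  vels <- cfg$velocities
  lo <- cfg$end_angle - min(0, cfg$threshold_velocity_slope * max(vels)) + 1
  hi <- cfg$start_angle - max(0, cfg$threshold_velocity_slope * max(vels)) - 0.3
  out_o <- out_c <- matrix(NA_real_, n_subjects, length(vels),
                           dimnames = list(NULL, vels))
  theta <- lat <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    theta[s] <- min(hi, max(lo, stats::rnorm(1, theta_mean, theta_sd)))
    lat[s] <- rtruncnorm1(cfg$h_latency_mean, cfg$h_latency_sd,
                          cfg$h_latency_range)
    cfg_s <- cfg
    cfg_s$true_threshold_angle <- theta[s]
    for (j in seq_along(vels)) {
      t_cross <- threshold_crossing_time(vels[j], cfg_s)
      t_onset <- t_cross + lat[s] +
        stats::rnorm(cfg$n_trials_per_velocity, 0, onset_jitter_sd)
      t_grid <- seq(0, t_cross + 0.2, by = 1 / cfg$sampling_rate)
      ang <- commanded_angle(t_grid, vels[j], cfg_s)
      srt <- stats::approx(t_grid, ang, xout = pmin(t_onset, max(t_grid)),
                           rule = 2)$y
      srt_c <- stats::approx(t_grid, ang,
                             xout = pmin(pmax(t_onset - lat[s], 0), max(t_grid)),
                             rule = 2)$y
      out_o[s, j] <- stats::median(srt)
      out_c[s, j] <- stats::median(srt_c)
    }
  }
  list(original = out_o, corrected = out_c, theta = theta, latency_s = lat)
}
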