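#' Zero-phase Butterworth band-pass filter for EMG
#'
#' Order-4 Butterworth applied forward-backward (zero phase), so filtering
#' adds no group delay and onset times read off the filtered trace are not
#' biased late. Default band 20-195 Hz, the off-line surface-EMG analysis
#' band.
#'
#' @param x Numeric EMG trace.
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered trace, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 100 * seq(0, 1, by = 1 / 2000))
#' y <- bandpass_emg(x, 2000)
#' @export
bandpass_emg <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_cut >= fs / 2) {
    stop("high_cut must be below the Nyquist frequency", call. = FALSE)
  }
  if (length(x) <= 3 * spec$order) {
    stop("trace too short to filter (need > 3 x filter order samples)",
         call. = FALSE)
  }
  bf <- signal::butter(spec$order / 2,
                       c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  if (spec$zero_phase) {
    signal::filtfilt(bf, x)
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Band-pass filter the EMG channels of a trial table
#'
#' Applies [bandpass_emg()] to every `emg_*` column of each nested trace.
#'
#' @param trials A nested trial tibble (as produced by [simulate_subject()]
#'   or [read_subject()]), with a `data` list-column.
#' @param fs Sampling rate (Hz); if `NULL`, inferred from the time grid.
#' @param spec A [filter_spec()].
#' @return The trial tibble with filtered traces.
#' @export
filter_trials <- function(trials, fs = NULL, spec = filter_spec()) {
  trials$data <- purrr::map(trials$data, function(tr) {
    fs_i <- fs %||% infer_fs(tr$time_s)
    dplyr::mutate(tr, dplyr::across(dplyr::starts_with("emg_"),
                                    ~ bandpass_emg(.x, fs_i, spec)))
  })
  trials
}

infer_fs <- function(time_s) {
  dt <- diff(time_s)
  if (any(abs(dt - dt[1]) > 1e-9)) {
    stop("time grid is not uniform", call. = FALSE)
  }
  1 / dt[1]
}

#' Sliding-window RMS of a trace
#'
#' Right-aligned window of `window` seconds, evaluated at every sample whose
#' trailing window fits inside the trace.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param window Window length (s).
#' @return RMS values, one per admissible endpoint (length
#'   `length(x) - L + 1` with `L` the window in samples).
#' @export
sliding_rms <- function(x, fs, window) {
  L <- max(1L, round(window * fs))
  if (length(x) < L) stop("trace shorter than the RMS window", call. = FALSE)
  cs <- cumsum(c(0, x^2))
  sqrt((cs[(L + 1):length(cs)] - cs[1:(length(cs) - L)]) / L)
}

#' Reject trials with pre-stretch background activation
#'
#' Implements the 5%-of-MVC rule: a trial is discarded when, for either
#' muscle, the maximum RMS over a 200 ms sliding window evaluated in the
#' 500 ms preceding the stretch exceeds `mvc_fraction` of that muscle's MVC
#' RMS. One contaminated muscle rejects the whole trial, and the reason is
#' recorded.
#'
#' @param trials Nested trial tibble (filter first with [filter_trials()]).
#' @param mvc_rms Named per-muscle MVC RMS vector (amplitude units), e.g.
#'   `c(sol = 1, mg = 1)`.
#' @param spec A [rejection_spec()].
#' @return The trial tibble with logical `kept`, character `reject_reason`
#'   and numeric `max_pre_rms_frac` (worst-muscle pre-stretch RMS as a
#'   fraction of MVC) columns appended.
#' @examples
#' subj <- simulate_subject(sim_config(n_trials_per_velocity = 1, rng_seed = 1))
#' kept <- reject_trials(filter_trials(subj$trials), subj$mvc_rms)
#' kept$kept
#' @export
reject_trials <- function(trials, mvc_rms, spec = rejection_spec()) {
  stopifnot(inherits(spec, "rejection_spec"))
  if (nrow(trials) == 0) {
    return(dplyr::mutate(trials, kept = logical(0),
                         reject_reason = character(0),
                         max_pre_rms_frac = numeric(0)))
  }
  res <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials$data[[i]]
    fs <- infer_fs(tr$time_s)
    onset <- trials$stretch_onset_s[i]
    pre <- tr[tr$time_s >= onset - spec$pre_window & tr$time_s < onset, ]
    if (nrow(pre) < round(spec$rms_window * fs)) {
      stop("trial ", trials$trial_id[i], " has less than pre_window of data ",
           "before stretch onset", call. = FALSE)
    }
    muscles <- sub("^emg_", "", grep("^emg_", names(tr), value = TRUE))
    missing_mvc <- setdiff(muscles, names(mvc_rms))
    if (length(missing_mvc) > 0) {
      stop("missing mvc_rms for muscle(s): ", paste(missing_mvc, collapse = ", "),
           call. = FALSE)
    }
    frac <- vapply(muscles, function(m) {
      max(sliding_rms(pre[[paste0("emg_", m)]], fs, spec$rms_window)) /
        mvc_rms[[m]]
    }, numeric(1))
    worst <- which.max(frac)
    bad <- frac > spec$mvc_fraction
    tibble::tibble(
      kept = !any(bad),
      reject_reason = if (any(bad)) {
        sprintf("pre-stretch %s RMS %.1f%% MVC exceeds %.0f%%",
                paste(muscles[bad], collapse = "+"),
                100 * max(frac), 100 * spec$mvc_fraction)
      } else NA_character_,
      max_pre_rms_frac = frac[[worst]]
    )
  })
  dplyr::bind_cols(trials, res)
}
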