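#' Write a subject's trials to delimited text
#'
#' One CSV per trial (`time_s`, `angle_deg`, `emg_sol`, `emg_mg`), a
#' `manifest.csv` with one row per trial (file, nominal velocity, stretch
#' onset and any truth columns), and a `subject.yml` with the per-muscle
#' H-reflex latencies, MVC RMS references and the generating configuration.
#'
#' @param subject An `srt_subject` (see [simulate_subject()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "srt_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- subject$trials
  files <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    files[i] <- paste0(trials$trial_id[i], ".csv")
    readr::write_csv(trials$data[[i]], file.path(dir, files[i]))
  }
  manifest <- dplyr::mutate(dplyr::select(trials, -"data"),
                            file = files, .before = 1)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  meta <- list(
    subject_id = subject$subject_id,
    h_latency_s = as.list(subject$h_latency_s),
    mvc_rms = as.list(subject$mvc_rms),
    config = unclass_config(subject$config)
  )
  yaml::write_yaml(meta, file.path(dir, "subject.yml"), precision = 15)
  invisible(dir)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$latency <- as.list(out$latency)
  out$mvc_rms <- as.list(out$mvc_rms)
  out
}

#' Read a subject written by [write_subject()]
#'
#' @param dir Directory holding `manifest.csv`, `subject.yml` and the trial
#'   CSVs.
#' @return An `srt_subject` with nested trial traces.
#' @export
read_subject <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "subject.yml"))
  trials <- dplyr::mutate(
    manifest,
    data = purrr::map(.data$file, ~ readr::read_csv(file.path(dir, .x),
                                                    show_col_types = FALSE))
  )
  trials <- dplyr::select(trials, -"file")
  structure(
    list(subject_id = meta$subject_id,
         trials = tibble::as_tibble(trials),
         h_latency_s = unlist(meta$h_latency_s),
         mvc_rms = unlist(meta$mvc_rms),
         config = meta$config),
    class = "srt_subject"
  )
}
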