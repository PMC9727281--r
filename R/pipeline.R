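#' Analyze one subject: filter, reject, detect, threshold, regress
#'
#' Runs the full single-subject pipeline: band-pass filtering of the EMG,
#' background-activation trial rejection, AGLR onset detection with
#' sustained-threshold fallback, per-trial SRT / latency-corrected SRT,
#' per-velocity medians, and the velocity-SRT regression per muscle and
#' method. A subject lacking an SRT median at any required velocity yields
#' `NULL` regressions for that muscle with the exclusion reason logged.
#'
#' @param subject An `srt_subject` ([simulate_subject()] or
#'   [read_subject()]).
#' @param filter A [filter_spec()].
#' @param rejection A [rejection_spec()].
#' @param aglr An [aglr_spec()].
#' @param required_velocities Velocities each muscle must cover (default:
#'   the distinct trial velocities).
#' @param max_disagreement Onset reconciliation tolerance (s).
#' @return A list of class `srt_subject_result`: `srt_table`, `medians`,
#'   `regressions` (tibble from [fit_velocity_regressions()], possibly with
#'   excluded muscles absent), `rejections`, `onsets`, `log` (character),
#'   `subject_id`, `h_latency_s`.
#' @examples
#' subj <- simulate_subject(sim_config(n_trials_per_velocity = 2, rng_seed = 11))
#' res <- analyze_subject(subj)
#' res$regressions
#' @export
analyze_subject <- function(subject,
                            filter = filter_spec(),
                            rejection = rejection_spec(),
                            aglr = aglr_spec(),
                            required_velocities = NULL,
                            max_disagreement = 0.02) {
  stopifnot(inherits(subject, "srt_subject"))
  req <- required_velocities %||% sort(unique(subject$trials$velocity))
  log <- character()

  trials <- filter_trials(subject$trials, spec = filter)
  trials <- reject_trials(trials, subject$mvc_rms, rejection)
  rejected <- trials[!trials$kept, c("trial_id", "velocity", "reject_reason")]
  if (nrow(rejected) > 0) {
    log <- c(log, sprintf("discarded %s (%g deg/s): %s", rejected$trial_id,
                          rejected$velocity, rejected$reject_reason))
  }

  onsets <- detect_onsets(trials, aglr, max_disagreement)
  overridden <- onsets[onsets$review & !is.na(onsets$note), ]
  if (nrow(overridden) > 0) {
    log <- c(log, sprintf("onset override %s/%s: %s", overridden$trial_id,
                          overridden$muscle, overridden$note))
  }

  srt_table <- compute_srt_table(trials, onsets, subject$h_latency_s)
  medians <- aggregate_medians(srt_table, required_velocities = req)

  regs <- purrr::map_dfr(unique(medians$muscle), function(m) {
    tryCatch(
      fit_velocity_regressions(medians[medians$muscle == m, ],
                               required_velocities = req),
      error = function(e) {
        log <<- c(log, sprintf("subject %s muscle %s excluded: %s",
                               subject$subject_id, m, conditionMessage(e)))
        NULL
      }
    )
  })

  structure(
    list(subject_id = subject$subject_id,
         h_latency_s = subject$h_latency_s,
         srt_table = srt_table, medians = medians,
         regressions = regs, rejections = rejected, onsets = onsets,
         log = log),
    class = "srt_subject_result"
  )
}

#' @export
print.srt_subject_result <- function(x, ...) {
  cat(sprintf("<srt_subject_result %s> %d SRT estimates, %d rejections, %d log lines\n",
              x$subject_id, nrow(x$srt_table), nrow(x$rejections), length(x$log)))
  if (nrow(x$regressions) > 0) print(dplyr::select(x$regressions, -"fit"))
  invisible(x)
}

#' Analyze a cohort and run the group-level comparisons
#'
#' Applies [analyze_subject()] to each subject, assembles per-subject slope,
#' TSRT and R-squared tables, and runs the group statistics: routed paired
#' comparisons (original vs latency-corrected) per muscle for slope, TSRT
#' and R-squared, and the Friedman velocity effect per muscle and method on
#' the complete subjects-by-velocities median matrices.
#'
#' @param subjects List of `srt_subject` objects (e.g. [simulate_cohort()]).
#' @param ... Passed to [analyze_subject()].
#' @param alpha Significance level for the group statistics.
#' @return A list of class `srt_cohort_result`: `subject_results`,
#'   `regression_table` (one row per subject x muscle x method),
#'   `median_table`, `method_comparisons`, `velocity_effects` (tidied
#'   tibble), `log`.
#' @export
analyze_cohort <- function(subjects, ..., alpha = 0.05) {
  results <- purrr::map(subjects, analyze_subject, ...)

  reg_table <- purrr::map_dfr(results, function(r) {
    if (nrow(r$regressions) == 0) return(NULL)
    dplyr::mutate(dplyr::select(r$regressions, -"fit"),
                  subject_id = r$subject_id, .before = 1)
  })
  med_table <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(r$medians, subject_id = r$subject_id, .before = 1)
  })

  comparisons <- NULL
  effects <- NULL
  if (nrow(reg_table) > 0) {
    comparisons <- purrr::map_dfr(unique(reg_table$muscle), function(m) {
      wide <- tidyr::pivot_wider(
        reg_table[reg_table$muscle == m,
                  c("subject_id", "method", "slope", "intercept_tsrt", "r_squared")],
        names_from = "method",
        values_from = c("slope", "intercept_tsrt", "r_squared"))
      wide <- wide[stats::complete.cases(wide), ]
      if (nrow(wide) < 3) return(NULL)
      dplyr::bind_rows(
        dplyr::mutate(compare_paired(wide$slope_original, wide$slope_corrected,
                                     alpha, "slope"), muscle = m),
        dplyr::mutate(compare_paired(wide$intercept_tsrt_original,
                                     wide$intercept_tsrt_corrected,
                                     alpha, "tsrt"), muscle = m),
        dplyr::mutate(compare_paired(wide$r_squared_original,
                                     wide$r_squared_corrected,
                                     alpha, "r_squared"), muscle = m)
      )
    })

    effects <- purrr::map_dfr(unique(med_table$muscle), function(m) {
      purrr::map_dfr(c("original", "corrected"), function(meth) {
        col <- if (meth == "original") "srt_median" else "srt_corrected_median"
        # only subjects analyzed at all velocities enter the velocity effect
        keep_ids <- reg_table$subject_id[reg_table$muscle == m &
                                           reg_table$method == meth]
        sub <- med_table[med_table$muscle == m &
                           med_table$subject_id %in% keep_ids, ]
        if (nrow(sub) == 0) return(NULL)
        wide <- tidyr::pivot_wider(sub[, c("subject_id", "velocity", col)],
                                   names_from = "velocity",
                                   values_from = dplyr::all_of(col))
        mat <- as.matrix(wide[, -1])
        if (nrow(mat) < 3 || any(!is.finite(mat))) return(NULL)
        tidy(velocity_effect(mat, alpha, muscle = m, method = meth))
      })
    })
  }

  structure(
    list(subject_results = results,
         regression_table = reg_table,
         median_table = med_table,
         method_comparisons = comparisons,
         velocity_effects = effects,
         log = unlist(purrr::map(results, "log"))),
    class = "srt_cohort_result"
  )
}

#' @export
print.srt_cohort_result <- function(x, ...) {
  cat(sprintf("<srt_cohort_result> %d subjects\n", length(x$subject_results)))
  if (!is.null(x$method_comparisons)) {
    cat("method comparisons (original vs corrected):\n")
    print(dplyr::select(x$method_comparisons, "muscle", "variable", "test_used",
                        "p_value", "effect_size_g"))
  }
  invisible(x)
}

#' Simulate a cohort to disk
#'
#' Writes each simulated subject into its own subdirectory plus a cohort
#' manifest listing the subject directories.
#'
#' @param cfg A [sim_config()] (use `rng_seed` for reproducibility).
#' @param n_subjects Number of subjects.
#' @param out_dir Output directory.
#' @return Tibble manifest (subject_id, dir), invisibly; also written as
#'   `cohort.csv` under `out_dir`.
#' @export
srt_simulate <- function(cfg, n_subjects, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- simulate_cohort(cfg, n_subjects)
  manifest <- purrr::map_dfr(subjects, function(s) {
    d <- file.path(out_dir, s$subject_id)
    write_subject(s, d)
    tibble::tibble(subject_id = s$subject_id, dir = s$subject_id)
  })
  readr::write_csv(manifest, file.path(out_dir, "cohort.csv"))
  invisible(manifest)
}

#' Analyze a cohort directory written by [srt_simulate()]
#'
#' @param data_dir Directory holding `cohort.csv` and subject folders.
#' @param out_dir Where to write the result tables (`srt_trials.csv`,
#'   `regressions.csv`, `method_comparisons.csv`, `velocity_effects.csv`,
#'   `pipeline_log.txt`).
#' @param ... Passed to [analyze_cohort()] / [analyze_subject()].
#' @return The `srt_cohort_result`, invisibly.
#' @export
srt_analyze <- function(data_dir, out_dir, ...) {
  manifest <- readr::read_csv(file.path(data_dir, "cohort.csv"),
                              show_col_types = FALSE)
  subjects <- purrr::map(manifest$dir,
                         ~ read_subject(file.path(data_dir, .x)))
  res <- analyze_cohort(subjects, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trial_tbl <- purrr::map_dfr(res$subject_results, function(r) {
    dplyr::mutate(r$srt_table, subject_id = r$subject_id, .before = 1)
  })
  readr::write_csv(trial_tbl, file.path(out_dir, "srt_trials.csv"))
  readr::write_csv(res$median_table, file.path(out_dir, "srt_medians.csv"))
  if (nrow(res$regression_table) > 0) {
    readr::write_csv(res$regression_table, file.path(out_dir, "regressions.csv"))
  }
  if (!is.null(res$method_comparisons)) {
    readr::write_csv(res$method_comparisons,
                     file.path(out_dir, "method_comparisons.csv"))
  }
  if (!is.null(res$velocity_effects)) {
    readr::write_csv(res$velocity_effects,
                     file.path(out_dir, "velocity_effects.csv"))
  }
  writeLines(res$log %||% character(), file.path(out_dir, "pipeline_log.txt"))
  invisible(res)
}

#' Render a plain-text summary of an analyzed cohort
#'
#' Median (IQR) SRT per velocity, muscle and method, plus slope / R-squared /
#' TSRT group summaries — the per-velocity layout of a cohort results table.
#'
#' @param results_dir Directory written by [srt_analyze()].
#' @return Character vector of report lines (also printed).
#' @export
srt_report <- function(results_dir) {
  med_path <- file.path(results_dir, "srt_medians.csv")
  if (!file.exists(med_path)) {
    warning("no result tables found under ", results_dir, call. = FALSE)
    return(invisible(character()))
  }
  med <- readr::read_csv(med_path, show_col_types = FALSE)
  lines <- c("Effects of stretch velocity on SRT (median (IQR) across subjects)")
  if (nrow(med) == 0) {
    warning("empty result tables", call. = FALSE)
    return(invisible(lines))
  }
  grp <- med |>
    tidyr::pivot_longer(c("srt_median", "srt_corrected_median"),
                        names_to = "method", values_to = "srt") |>
    dplyr::mutate(method = ifelse(.data$method == "srt_median",
                                  "SRT", "SRT_corrected")) |>
    dplyr::group_by(.data$muscle, .data$method, .data$velocity) |>
    dplyr::summarise(
      label = sprintf("%.0f (%.0f)",
                      stats::median(.data$srt, na.rm = TRUE),
                      stats::IQR(.data$srt, na.rm = TRUE)),
      .groups = "drop")
  for (i in seq_len(nrow(grp))) {
    lines <- c(lines, sprintf("  %-3s %-13s %3g deg/s: %s", grp$muscle[i],
                              grp$method[i], grp$velocity[i], grp$label[i]))
  }
  reg_path <- file.path(results_dir, "regressions.csv")
  if (file.exists(reg_path)) {
    reg <- readr::read_csv(reg_path, show_col_types = FALSE)
    lines <- c(lines, "Velocity-SRT regressions (group means)")
    sm <- reg |>
      dplyr::group_by(.data$muscle, .data$method) |>
      dplyr::summarise(
        slope = mean(.data$slope), tsrt = mean(.data$intercept_tsrt),
        r2 = stats::median(.data$r_squared), .groups = "drop")
    for (i in seq_len(nrow(sm))) {
      lines <- c(lines, sprintf("  %-3s %-9s slope %+.4f, TSRT %.1f deg, median R^2 %.2f",
                                sm$muscle[i], sm$method[i], sm$slope[i],
                                sm$tsrt[i], sm$r2[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
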