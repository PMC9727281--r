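#' Plot a trial's angle trajectory and EMG channels
#'
#' Angle and both EMG traces against time, with the stretch onset and (when
#' truth is available) the true mechanical and EMG reflex onsets marked.
#'
#' @param trial One row of a nested trial tibble.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial) {
  stopifnot(nrow(trial) == 1)
  tr <- trial$data[[1]]
  long <- tidyr::pivot_longer(tr, -"time_s", names_to = "channel",
                              values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::geom_vline(xintercept = trial$stretch_onset_s,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s, %g deg/s", trial$trial_id,
                                  trial$velocity))
  if ("true_sr_onset_s" %in% names(trial) && is.finite(trial$true_sr_onset_s)) {
    p <- p + ggplot2::geom_vline(xintercept = trial$true_sr_onset_s,
                                 colour = "firebrick", linetype = "dotted")
  }
  p
}

#' @rdname fit_velocity_regression
#' @exportS3Method ggplot2::autoplot
autoplot.velocity_regression <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$velocity, y = .data$srt)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE, colour = "steelblue",
                         linewidth = 0.6) +
    ggplot2::expand_limits(x = 0) +
    ggplot2::annotate("point", x = 0, y = object$intercept_tsrt,
                      shape = 4, size = 3, colour = "firebrick") +
    ggplot2::labs(x = "stretch velocity (deg/s)",
                  y = "median SRT (deg plantarflexion)",
                  title = sprintf("slope %+.4f (%s), TSRT %.1f deg, R^2 %.2f",
                                  object$slope, object$dependence_class,
                                  object$intercept_tsrt, object$r_squared))
}

#' Plot per-subject velocity-SRT medians for both methods
#'
#' One panel per muscle: per-velocity median SRTs (original and
#' latency-corrected) with their regression lines extrapolated to zero
#' velocity, visualizing how the correction rotates the regression towards
#' a velocity-independent threshold.
#'
#' @param medians Output of [aggregate_medians()].
#' @return A ggplot object.
#' @export
plot_srt_medians <- function(medians) {
  long <- medians |>
    tidyr::pivot_longer(c("srt_median", "srt_corrected_median"),
                        names_to = "method", values_to = "srt") |>
    dplyr::mutate(method = ifelse(.data$method == "srt_median",
                                  "original", "corrected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$velocity, y = .data$srt,
                                     colour = .data$method,
                                     shape = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         fullrange = TRUE, linewidth = 0.6) +
    ggplot2::expand_limits(x = 0) +
    ggplot2::facet_wrap(~muscle) +
    ggplot2::labs(x = "stretch velocity (deg/s)",
                  y = "median SRT (deg plantarflexion)",
                  colour = NULL, shape = NULL)
}
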