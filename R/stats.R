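#' Hedges' g with small-sample correction
#'
#' Standardized mean difference between two sets of paired observations,
#' using the pooled SD and the small-sample bias correction
#' \eqn{J = 1 - 3/(4\,df - 1)} with \eqn{df = 2n - 2}.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Hedges' g (signed).
#' @examples
#' hedges_g(rnorm(12, 1), rnorm(12, 0))
#' @export
hedges_g <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  sp <- sqrt(((n - 1) * stats::var(x) + (n - 1) * stats::var(y)) / (2 * n - 2))
  if (sp == 0) return(0)
  df <- 2 * n - 2
  ((mean(x) - mean(y)) / sp) * (1 - 3 / (4 * df - 1))
}

#' Paired comparison with normality-based routing
#'
#' Compares two paired sets of per-subject values (e.g. regression slopes
#' with and without latency correction). The paired differences are tested
#' for normality (Shapiro-Wilk at `alpha`); normal differences are compared
#' with the two-sided paired t-test, non-normal ones with the Wilcoxon
#' signed-rank test. Equality of variances is reported via Levene's test.
#' Effect size is Hedges' g ([hedges_g()]).
#'
#' Degenerate inputs: an all-zero difference vector yields `p = 1`, g = 0 on
#' the t route with a degeneracy flag; a constant non-zero difference routes
#' to Wilcoxon with the flag set.
#'
#' @param x,y Paired per-subject values (equal length, n >= 3).
#' @param alpha Significance level for the normality gate (default 0.05).
#' @param variable Optional label stored in the output.
#' @return One-row tibble: `variable`, `n`, `test_used`, `statistic`,
#'   `p_value`, `effect_size_g`, `conf_low`, `conf_high`, `shapiro_p`,
#'   `levene_p`, `degenerate`, and a formatted `summary_x` / `summary_y`
#'   (mean +/- SD when normal, median (IQR) otherwise).
#' @examples
#' compare_paired(rnorm(12, 0.014, 0.012), rnorm(12, -0.01, 0.012))
#' @export
compare_paired <- function(x, y, alpha = 0.05, variable = NA_character_) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  d <- x - y
  # floating-point-tolerant constancy check for the degenerate branches
  degenerate <- stats::sd(d) < 1e-10 * max(1, abs(mean(d)))

  if (degenerate && all(abs(d) < 1e-12)) {
    test_used <- "paired_t"; statistic <- 0; p <- 1
    ci <- c(NA_real_, NA_real_); shapiro_p <- NA_real_
  } else if (degenerate) {
    test_used <- "wilcoxon"
    wt <- suppressWarnings(stats::wilcox.test(d, conf.int = TRUE))
    statistic <- unname(wt$statistic); p <- wt$p.value
    ci <- unname(wt$conf.int); shapiro_p <- NA_real_
  } else {
    shapiro_p <- stats::shapiro.test(d)$p.value
    if (shapiro_p >= alpha) {
      test_used <- "paired_t"
      tt <- stats::t.test(x, y, paired = TRUE)
      statistic <- unname(tt$statistic); p <- tt$p.value
      ci <- unname(tt$conf.int)
    } else {
      test_used <- "wilcoxon"
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                conf.int = TRUE))
      statistic <- unname(wt$statistic); p <- wt$p.value
      ci <- unname(wt$conf.int)
    }
  }

  lev <- tryCatch({
    df <- data.frame(v = c(x, y),
                     g = factor(rep(c("x", "y"), times = c(n, n))))
    car::leveneTest(v ~ g, data = df)[1, "Pr(>F)"]
  }, error = function(e) NA_real_)

  normal <- !is.na(shapiro_p) && shapiro_p >= alpha
  fmt <- function(v) {
    if (normal) sprintf("%.3g ± %.3g", mean(v), stats::sd(v))
    else sprintf("%.3g (%.3g)", stats::median(v), stats::IQR(v))
  }
  tibble::tibble(
    variable = variable, n = n, test_used = test_used,
    statistic = statistic, p_value = p,
    effect_size_g = hedges_g(x, y),
    conf_low = ci[1], conf_high = ci[2],
    shapiro_p = shapiro_p, levene_p = lev,
    degenerate = degenerate,
    summary_x = fmt(x), summary_y = fmt(y)
  )
}

#' Effect of stretch velocity on the SRT (Friedman + Bonferroni post hoc)
#'
#' Friedman omnibus test on a complete subjects-by-velocities matrix of
#' median SRTs; when the omnibus is significant at `alpha`, all pairwise
#' velocity contrasts are tested with the Wilcoxon signed-rank test and
#' Bonferroni-adjusted (6 comparisons for 4 velocities).
#'
#' @param srt_matrix Numeric matrix (or data frame), rows = subjects,
#'   columns = velocities (column names taken as velocity labels). Must be
#'   complete: subjects missing a velocity are excluded upstream.
#' @param alpha Significance level gating the post hoc (default 0.05).
#' @param muscle,method Optional labels stored in the result.
#' @return A `velocity_effect` object: list with `friedman_statistic`, `df`,
#'   `p_value`, `n_subjects`, `posthoc` (tibble of pairwise contrasts with
#'   raw and Bonferroni-adjusted p, or NULL when the omnibus is not
#'   significant), plus labels. Has a [tidy()] method.
#' @examples
#' m <- matrix(rnorm(48, 15), 12, 4, dimnames = list(NULL, c(55, 110, 210, 291)))
#' velocity_effect(m)
#' @export
velocity_effect <- function(srt_matrix, alpha = 0.05,
                            muscle = NA_character_, method = NA_character_) {
  m <- as.matrix(srt_matrix)
  if (any(!is.finite(m))) {
    stop("incomplete matrix: subjects without all velocities must be ",
         "excluded before testing", call. = FALSE)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("v", seq_len(ncol(m)))
  ft <- stats::friedman.test(m)
  # completely tied data (e.g. constant rows) yield an undefined statistic:
  # there is no velocity effect, report p = 1
  if (!is.finite(ft$p.value)) {
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  posthoc <- NULL
  if (ft$p.value < alpha) {
    pairs <- utils::combn(ncol(m), 2)
    n_cmp <- ncol(pairs)
    posthoc <- purrr::map_dfr(seq_len(n_cmp), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      wt <- suppressWarnings(stats::wilcox.test(m[, i1], m[, i2],
                                                paired = TRUE))
      tibble::tibble(velocity_a = colnames(m)[i1],
                     velocity_b = colnames(m)[i2],
                     statistic = unname(wt$statistic),
                     p_raw = wt$p.value,
                     p_bonferroni = min(1, wt$p.value * n_cmp),
                     significant = min(1, wt$p.value * n_cmp) < alpha)
    })
  }
  structure(
    list(muscle = muscle, method = method,
         friedman_statistic = unname(ft$statistic),
         df = unname(ft$parameter), p_value = ft$p.value,
         n_subjects = nrow(m), alpha = alpha, posthoc = posthoc),
    class = "velocity_effect"
  )
}

#' @export
print.velocity_effect <- function(x, ...) {
  cat(sprintf("<velocity_effect%s> Friedman chi^2(%d) = %.2f, p = %.4g (n = %d)\n",
              if (!is.na(x$muscle)) paste0(" ", x$muscle, "/", x$method) else "",
              x$df, x$friedman_statistic, x$p_value, x$n_subjects))
  if (!is.null(x$posthoc)) {
    cat("  Bonferroni post hoc:\n")
    print(x$posthoc)
  } else {
    cat("  omnibus not significant; no post hoc\n")
  }
  invisible(x)
}

#' @rdname velocity_effect
#' @param x A `velocity_effect`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.velocity_effect <- function(x, ...) {
  omnibus <- tibble::tibble(
    muscle = x$muscle, method = x$method, contrast = "omnibus",
    statistic = x$friedman_statistic, p_value = x$p_value,
    p_adjusted = x$p_value, significant = x$p_value < x$alpha
  )
  if (is.null(x$posthoc)) return(omnibus)
  dplyr::bind_rows(
    omnibus,
    dplyr::transmute(x$posthoc,
                     muscle = x$muscle, method = x$method,
                     contrast = paste(.data$velocity_a, "vs", .data$velocity_b),
                     statistic = .data$statistic, p_value = .data$p_raw,
                     p_adjusted = .data$p_bonferroni,
                     significant = .data$significant)
  )
}
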