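# Shared fixtures and independent oracles, all built in code at test time.

# small, fast configuration for pipeline-level tests
quick_cfg <- function(...) {
  sim_config(n_trials_per_velocity = 3, ...)
}

# Exhaustive single-change-point ML search over the WHOLE trace: for every
# candidate j after the search start, the log-likelihood ratio of "variance
# sigma1 from j to the end" against "all baseline variance". Independent of
# the windowed AGLR implementation path.
exhaustive_changepoint <- function(x, baseline_idx, search_from) {
  x <- x - mean(x[baseline_idx])
  s0 <- mean(x[baseline_idx]^2)
  n <- length(x)
  cs <- cumsum(c(0, x^2))
  js <- seq.int(search_from, n - 1L)
  nj <- n - js + 1L
  rj <- (cs[n + 1L] - cs[js]) / nj / s0
  score <- ifelse(rj > 1, (nj / 2) * (rj - log(rj) - 1), 0)
  js[which.max(score)]
}

# deterministic zero-mean trace with an exact variance step at sample s0:
# alternating +/- sigma0 then +/- sigma1
step_variance_trace <- function(n, s0_idx, sigma0, sigma1) {
  signs <- rep_len(c(1, -1), n)
  amp <- c(rep(sigma0, s0_idx - 1), rep(sigma1, n - s0_idx + 1))
  signs * amp
}

# per-row OLS slope/intercept of a subjects-by-velocities median matrix
row_regressions <- function(m) {
  v <- as.numeric(colnames(m))
  t(apply(m, 1, function(y) {
    fit <- stats::lm(y ~ v)
    c(slope = unname(stats::coef(fit)[2]),
      tsrt = unname(stats::coef(fit)[1]))
  }))
}

# subject with only the soleus channel kept (halves onset-detection work)
sol_only <- function(subject) {
  subject$trials$data <- lapply(subject$trials$data,
                                function(d) d[, c("time_s", "angle_deg", "emg_sol")])
  subject$h_latency_s <- subject$h_latency_s["sol"]
  subject$mvc_rms <- subject$mvc_rms["sol"]
  subject
}
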