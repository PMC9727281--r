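test_that("angle interpolation matches the closed-form trajectory", {
  cfg <- sim_config(rng_seed = 41)
  set.seed(41)
  tr <- simulate_trial(cfg, 110)
  d <- tr$data[[1]]
  # pre-stretch plateau
  expect_equal(angle_at_time(d, 0.3), 20)
  # exact at sample grid points
  expect_equal(angle_at_time(d, d$time_s[1000]), d$angle_deg[1000])
  # 50 ms after ramp start (past the 30 ms acceleration): closed form
  # drop = 0.5*v*accel + v*(t - accel)
  want <- 20 - (0.5 * 110 * 0.030 + 110 * 0.020)
  expect_equal(angle_at_time(d, tr$stretch_onset_s + 0.050), want,
               tolerance = 1e-6)
  expect_error(angle_at_time(d, -1), "outside")
})

test_that("latency correction moves the SRT by latency x velocity", {
  # 55 deg/s with a 28 ms latency: 1.54 deg correction (prints as 1.5)
  cfg <- sim_config(rng_seed = 42)
  set.seed(42)
  tr <- simulate_trial(cfg, 55)
  est <- compute_srt(tr$data[[1]], tr$true_emg_onset_sol_s, 0.028)
  expect_equal(est$srt_corrected - est$srt, 1.54, tolerance = 0.02)
  expect_equal(round(est$srt_corrected - est$srt, 1), 1.5)

  # 300 deg/s with 30 ms: the 9 deg error
  cfg2 <- sim_config(velocities = c(55, 300), true_threshold_angle = 10,
                     latency = 0.030, rng_seed = 42)
  set.seed(42)
  tr2 <- simulate_trial(cfg2, 300)
  est2 <- compute_srt(tr2$data[[1]], tr2$true_emg_onset_sol_s, 0.030)
  expect_equal(est2$srt_corrected - est2$srt, 9, tolerance = 0.16)

  # zero latency: both methods identical
  est0 <- compute_srt(tr$data[[1]], tr$true_emg_onset_sol_s, 0)
  expect_identical(est0$srt, est0$srt_corrected)

  expect_error(compute_srt(tr$data[[1]], 0.01, 0.05), "before the start")
})

test_that("corrected SRT is never later in the stretch than the uncorrected SRT", {
  cfg <- sim_config(rng_seed = 43)
  set.seed(43)
  for (v in cfg$velocities) {
    tr <- simulate_trial(cfg, v)
    est <- compute_srt(tr$data[[1]], tr$true_emg_onset_sol_s, 0.028)
    expect_gte(est$srt_corrected, est$srt)
    expect_true(est$srt >= cfg$end_angle && est$srt_corrected <= cfg$start_angle)
  }
})

test_that("analytic latency-error and pathway-bound identities hold", {
  expect_equal(latency_error(0.030, 50), 1.5)
  expect_equal(latency_error(0.030, 300), 9)
  expect_equal(latency_error(0.5, 0), 0)
  expect_equal(round(latency_error(0.028, 55), 1), 1.5)

  b <- pathway_error_bound(0.028, 0.15, 291)
  expect_equal(unname(b["time_s"]), 0.0042)
  expect_equal(round(unname(b["angle_deg"]), 1), 1.2)
  expect_equal(unname(pathway_error_bound(0.030, 0.10, 300)),
               c(0.003, 0.9))
  expect_equal(unname(pathway_error_bound(0.028, 1e-9, 291)), c(0, 0),
               tolerance = 1e-6)
})

test_that("per-velocity medians use the midpoint convention and flag missing velocities", {
  est <- tibble::tibble(
    muscle = "sol",
    velocity = rep(c(55, 110), c(3, 2)),
    srt = c(10, 12, 14, 10, 20),
    srt_corrected = c(10, 12, 14, 10, 20) + 1
  )
  med <- aggregate_medians(est)
  expect_equal(med$srt_median, c(12, 15))
  expect_equal(med$srt_corrected_median, c(13, 16))

  med2 <- aggregate_medians(est, required_velocities = c(55, 110, 210, 291))
  expect_identical(nrow(med2), 4L)
  expect_identical(med2$n[med2$velocity == 210], 0L)
  expect_true(is.na(med2$srt_median[med2$velocity == 291]))
})

test_that("velocity regression recovers closed-form slope, TSRT and class", {
  v <- c(55, 110, 210, 291)
  med <- tibble::tibble(velocity = v, srt_median = 19 - 0.028 * v)
  fit <- fit_velocity_regression(med)
  expect_equal(fit$slope, -0.028, tolerance = 1e-10)
  expect_equal(fit$intercept_tsrt, 19, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$dependence_class, "negative")

  g <- glance(fit)
  expect_identical(g$n_velocities, 4L)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "velocity"))
})

test_that("degenerate and boundary slopes classify per the near-zero rule", {
  v <- c(55, 110, 210, 291)
  flat <- fit_velocity_regression(tibble::tibble(velocity = v, srt_median = 19))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_true(flat$zero_variance)
  expect_identical(flat$dependence_class, "near_zero")

  mk <- function(b) fit_velocity_regression(
    tibble::tibble(velocity = v, srt_median = 15 + b * v))
  expect_identical(mk(0.009)$dependence_class, "near_zero")
  expect_identical(mk(0.011)$dependence_class, "positive")
  expect_identical(mk(-0.011)$dependence_class, "negative")
})

test_that("regression is refused rather than fitted on incomplete velocities", {
  med <- tibble::tibble(velocity = c(55, 110, 210), srt_median = c(17, 16, 13))
  expect_error(fit_velocity_regression(med, required_velocities = c(55, 110, 210, 291)),
               "excluded")
  expect_error(fit_velocity_regression(med[1:2, ]), "at least 3")
})

test_that("built-in velocity dependence is recovered by the corrected fit", {
  cfg <- sim_config(true_threshold_angle = 15, threshold_velocity_slope = 0.01)
  set.seed(44)
  slopes <- replicate(100, {
    co <- simulate_srt_cohort(n_subjects = 1, cfg = cfg, theta_mean = 15,
                              theta_sd = 1)
    unname(row_regressions(co$corrected)[1, "slope"])
  })
  expect_lt(abs(mean(slopes) - 0.01), 0.002)   # bias < 20% of the true slope
})
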