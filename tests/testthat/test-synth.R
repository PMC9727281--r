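test_that("commanded trajectory reaches nominal velocity within 1% after acceleration", {
  cfg <- sim_config()
  for (v in cfg$velocities) {
    set.seed(1)
    tr <- simulate_trial(cfg, v)
    d <- tr$data[[1]]
    onset <- tr$stretch_onset_s
    range <- cfg$start_angle - cfg$end_angle
    accel_drop <- 0.5 * v * cfg$accel_duration
    t_end <- onset + cfg$accel_duration + (range - accel_drop) / v
    seg <- d$time_s > onset + cfg$accel_duration + 0.002 & d$time_s < t_end - 0.002
    fd_vel <- -diff(d$angle_deg[seg]) * cfg$sampling_rate
    expect_true(all(abs(fd_vel - v) / v < 0.01))
    # plateaus before the stretch and after the end of range
    expect_true(all(d$angle_deg[d$time_s <= onset] == cfg$start_angle))
    expect_true(all(abs(d$angle_deg[d$time_s > t_end + 0.002] - cfg$end_angle) < 1e-9))
    expect_true(all(diff(d$angle_deg) <= 1e-12))  # non-increasing
  }
})

test_that("reflex fires at the true threshold angle (within one angular sample step)", {
  cfg <- sim_config(true_threshold_angle = 15)
  for (v in cfg$velocities) {
    set.seed(2)
    tr <- simulate_trial(cfg, v)
    ang <- angle_at_time(tr$data[[1]], tr$true_sr_onset_s)
    expect_lt(abs(ang - 15), v / cfg$sampling_rate)
  }
})

test_that("EMG onset truth lags mechanical onset by exactly the configured latency", {
  cfg0 <- sim_config(latency = 0)
  set.seed(3)
  tr0 <- simulate_trial(cfg0, 110)
  expect_identical(tr0$true_emg_onset_sol_s, tr0$true_sr_onset_s)

  cfg <- sim_config(latency = c(sol = 0.028, mg = 0.031))
  set.seed(3)
  tr <- simulate_trial(cfg, 110)
  expect_equal(tr$true_emg_onset_sol_s - tr$true_sr_onset_s, 0.028)
  expect_equal(tr$true_emg_onset_mg_s - tr$true_sr_onset_s, 0.031)
})

test_that("angular displacement across a 30 ms latency at 300 deg/s is 9 degrees", {
  cfg <- sim_config(velocities = c(55, 300), true_threshold_angle = 10,
                    latency = 0.030)
  set.seed(4)
  tr <- simulate_trial(cfg, 300)
  d <- tr$data[[1]]
  err <- angle_at_time(d, tr$true_sr_onset_s) -
    angle_at_time(d, tr$true_emg_onset_sol_s)
  expect_lt(abs(err - 9), 300 / cfg$sampling_rate)
})

test_that("identical configuration and seed reproduce the dataset bit for bit", {
  cfg <- quick_cfg(rng_seed = 11, contamination_fraction = 0.25)
  s1 <- simulate_subject(cfg)
  s2 <- simulate_subject(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$h_latency_s, s2$h_latency_s)
})

test_that("subjects have the study's trial counts and contamination by construction", {
  full <- simulate_subject(sim_config(rng_seed = 5))
  expect_identical(nrow(full$trials), 40L)                  # 4 velocities x 10
  expect_equal(as.integer(table(full$trials$velocity)), rep(10L, 4))
  expect_false(any(full$trials$contaminated))               # fraction 0

  cont <- simulate_subject(sim_config(rng_seed = 6, contamination_fraction = 0.25))
  expect_identical(sum(cont$trials$contaminated), 10L)      # exactly 25% of 40

  empty <- simulate_subject(sim_config(n_trials_per_velocity = 0, rng_seed = 7))
  expect_identical(nrow(empty$trials), 0L)
})

test_that("subject H-reflex latencies stay in the physiological range and are shared across trials", {
  subj <- simulate_subject(quick_cfg(rng_seed = 8))
  expect_true(all(subj$h_latency_s >= 0.023 & subj$h_latency_s <= 0.035))
  lag <- subj$trials$true_emg_onset_sol_s - subj$trials$true_sr_onset_s
  expect_true(all(abs(lag - subj$h_latency_s[["sol"]]) < 1e-12))
})

test_that("a threshold outside the stretched range is refused", {
  expect_error(sim_config(true_threshold_angle = 21), "outside")
  expect_error(sim_config(true_threshold_angle = 15,
                          threshold_velocity_slope = 0.02),
               "outside")   # 15 + 0.02 * 291 > 20
})

test_that("H-reflex traces carry their truth and are quiet between artifact and H-wave", {
  tr <- simulate_hreflex(0.028, noise_sd = 0)
  expect_equal(attr(tr, "h_latency"), 0.028)
  quiet <- tr$emg[tr$time_s > 0.014 & tr$time_s < 0.0275]
  expect_true(all(quiet == 0))
  first_dev <- min(tr$time_s[tr$time_s >= 0.014 & abs(tr$emg) > 1e-9])
  expect_lt(abs(first_dev - 0.028), 1.5 / 2000)
  # both ends of the reported latency range are accepted
  expect_no_error(simulate_hreflex(0.023))
  expect_no_error(simulate_hreflex(0.035))
  expect_error(simulate_hreflex(0.060))
})

test_that("measurement-level cohorts are complete and recover the threshold when corrected", {
  set.seed(9)
  co <- simulate_srt_cohort(n_subjects = 8)
  expect_false(any(is.na(co$original)))
  expect_false(any(is.na(co$corrected)))
  # corrected medians sit at each subject's own threshold angle
  expect_true(all(abs(co$corrected - co$theta) < 1))
  # uncorrected medians are displaced to later (smaller) angles, worst at speed
  expect_true(all(co$original[, "291"] < co$corrected[, "291"]))
})
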