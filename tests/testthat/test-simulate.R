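test_that("the decision model matches the normal-CDF oracle", {
  # chance responder: d' = 0, threshold 0
  p0 <- quiet_profile(dprime = c(`385` = 0, `485` = 0, `585` = 0),
                      criterion = 0)
  spec_go <- as.list(make_spec(flight = 485)[1, ])
  spec_ng <- as.list(make_spec(flight = 485, location = 1L)[1, ])
  withr::with_seed(1, {
    tg <- mean(replicate(2000, simulate_decision(p0, spec_go)$touched))
    tn <- mean(replicate(2000, simulate_decision(p0, spec_ng)$touched))
  })
  expect_equal(tg, 0.5, tolerance = 0.06)
  expect_equal(tn, 0.5, tolerance = 0.06)

  # d' = 2, threshold 1: hit rate Phi(1), false-alarm rate Phi(-1)
  p2 <- quiet_profile(dprime = c(`385` = 2, `485` = 2, `585` = 2),
                      criterion = 1)
  withr::with_seed(2, {
    hr <- mean(replicate(4000, simulate_decision(p2, spec_go)$touched))
    fr <- mean(replicate(4000, simulate_decision(p2, spec_ng)$touched))
  })
  expect_equal(hr, pnorm(1), tolerance = 0.03)
  expect_equal(fr, pnorm(-1), tolerance = 0.03)

  # infinitely conservative threshold: never touches
  pc <- quiet_profile(criterion = 1e9)
  withr::with_seed(3, {
    expect_false(any(replicate(100, simulate_decision(pc, spec_go)$touched)))
  })
})

test_that("perfect pursuit glues gaze to the stimulus path", {
  p <- quiet_profile(pursuit_gain = 1, pursuit_lag_ms = 0,
                     saccade_latency_mean_ms = 0)
  spec <- as.list(make_spec(fixation = 390, flight = 585)[1, ])
  g <- withr::with_seed(1, simulate_gaze_trial(p, spec, GEOM))
  fl <- g$t_ms >= 390
  stim <- stimulus_position(spec, GEOM, pmin(g$t_ms[fl] - 390, 585))
  d <- sqrt((g$x[fl] - stim[, 1])^2 + (g$y[fl] - stim[, 2])^2)
  # brief saccade transient aside, gaze rides the stimulus
  expect_lt(max(d), 1.5)
  expect_true(all(d < 8))  # tracking fraction 100%
})

test_that("zero pursuit gain leaves gaze far from late stimulus positions", {
  p <- quiet_profile(pursuit_gain = 1e-9, saccade_latency_mean_ms = 150)
  # long trajectory: outer no-go location
  spec <- as.list(make_spec(fixation = 390, flight = 585, location = 1L)[1, ])
  g <- withr::with_seed(1, simulate_gaze_trial(p, spec, GEOM))
  endt <- max(g$t_ms)
  stim_end <- stimulus_position(spec, GEOM, 585)
  d_end <- sqrt((g$x[g$t_ms == endt] - stim_end[1, 1])^2 +
                  (g$y[g$t_ms == endt] - stim_end[1, 2])^2)
  expect_gt(d_end, 8)
})

test_that("pupil traces are flat without ramp/dilation and recover both", {
  pz <- quiet_profile(pupil_amplitude_mm = 0, pupil_fixation_slope_mm_s = 0)
  spec <- as.list(make_spec()[1, ])
  tr <- withr::with_seed(1, simulate_pupil_trial(pz, spec))
  expect_true(all(abs(tr$pupil_mm - pz$pupil_baseline_mm) < 1e-12))

  # noise-free ramp: OLS over fixation returns the generating slope
  ps <- quiet_profile(pupil_amplitude_mm = 0,
                      pupil_fixation_slope_mm_s = 0.25)
  tr <- withr::with_seed(1, simulate_pupil_trial(ps, spec))
  sl <- segment_slope(tr$t_ms, tr$pupil_mm, c(0, spec$fixation_duration_ms))
  expect_equal(sl, 0.25, tolerance = 1e-9)
  # diameter stays positive
  expect_true(all(tr$pupil_mm > 0))
})

test_that("no-touch hand traces never cross the 20 deg/s threshold", {
  p <- quiet_profile(criterion = 1e9)
  spec <- as.list(make_spec()[1, ])
  withr::with_seed(4, {
    for (i in 1:20) {
      dec <- simulate_decision(p, spec)
      h <- simulate_hand_trial(p, spec, GEOM, dec)
      expect_true(all(h$hand_speed < 20))
      expect_null(h$touch)
    }
  })
})

test_that("sessions are deterministic, sized by the schedule, with truth rows", {
  p <- subject_profile("control")
  sch <- generate_tpt_schedule(GEOM, blocks = 3, seed = 2)
  expect_equal(nrow(sch), 240L)
  s1 <- simulate_session(p, sch[1:10, ], GEOM, seed = 5)
  s2 <- simulate_session(p, sch[1:10, ], GEOM, seed = 5)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 10L)
  expect_setequal(unique(s1$traces$trial_id), sch$trial_id[1:10])
  # 200 Hz spacing within each trial
  dt <- tapply(s1$traces$t_ms, s1$traces$trial_id, function(t) unique(diff(t)))
  expect_true(all(unlist(dt) == 5))
})

test_that("reaction-time simulation honours the profile mean and filters", {
  p <- subject_profile("expert")
  sch <- generate_rtt_schedule(9)
  presses <- simulate_rtt_session(p, sch, seed = 10,
                                  anticipation_prob = 0, lapse_prob = 0)
  res <- rtt_reaction_times(presses$press_ms, sch)
  expect_equal(res$summary$n_included, 50L)
  expect_equal(res$summary$mean_rt_ms, 310, tolerance = 0.1 * 310)
})
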