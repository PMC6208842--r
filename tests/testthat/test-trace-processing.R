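test_that("angular velocity matches finite-difference oracles", {
  t <- seq(0, 1000, by = 5)
  n <- length(t)
  # constant position -> zero speed
  expect_true(all(angular_velocity(rep(1, n), rep(-2, n), t) == 0))
  # linear motion of 30 deg over 1 s -> 30 deg/s at interior samples
  v <- angular_velocity(30 * t / 1000, rep(0, n), t)
  expect_equal(v[4:(n - 3)], rep(30, n - 6), tolerance = 1e-9)
  # 5 deg step in one 5 ms interval: raw central difference spreads the
  # step over 2 intervals -> 5 deg / 10 ms = 500 deg/s; the one-sided
  # oracle value of 1000 deg/s appears with sub-sample differencing
  x <- c(rep(0, 100), rep(5, 101))
  v_raw <- angular_velocity(x, rep(0, 201), t, smooth_k = 1)
  expect_equal(max(v_raw), 500)
  expect_equal(max(diff(x) / 0.005), 1000)
  expect_lt(max(angular_velocity(x, rep(0, 201), t, smooth_k = 5)), 500)
  expect_error(angular_velocity(c(1, 2), c(1, 2)), "3 samples")
})

test_that("blink-free trials pass QC unchanged", {
  spec <- make_spec()
  tr <- flat_trace(spec)
  cl <- clean_traces(as_session(tr, spec), GEOM)
  expect_true(cl$trials$valid)
  expect_true(is.na(cl$trials$reason))
  expect_equal(cl$traces$gaze_x_deg, tr$gaze_x_deg)
})

test_that("blinks over critical windows or beyond the span limit invalidate", {
  spec <- make_spec(fixation = 890, flight = 485)
  tr <- flat_trace(spec)
  # 400 ms blink covering stimulus onset
  hit <- tr$t_ms >= 700 & tr$t_ms < 1100
  tr$blink[hit] <- TRUE
  tr$gaze_x_deg[hit] <- NA; tr$gaze_y_deg[hit] <- NA; tr$pupil_mm[hit] <- NA
  cl <- clean_traces(as_session(tr, spec), GEOM)
  expect_false(cl$trials$valid)
  expect_equal(cl$trials$reason, "blink")

  # short mid-fixation blink: interpolated, trial stays valid
  tr2 <- flat_trace(spec)
  hit2 <- tr2$t_ms >= 300 & tr2$t_ms < 400
  tr2$blink[hit2] <- TRUE
  tr2$gaze_x_deg[hit2] <- NA; tr2$gaze_y_deg[hit2] <- NA
  tr2$pupil_mm[hit2] <- NA
  cl2 <- clean_traces(as_session(tr2, spec), GEOM)
  expect_true(cl2$trials$valid)
  expect_false(anyNA(cl2$traces$gaze_x_deg))
})

test_that("excessive missingness invalidates a trial", {
  spec <- make_spec(fixation = 890, flight = 485)
  tr <- flat_trace(spec)
  # scattered short gaps totalling > 30% of samples, away from critical windows
  n <- nrow(tr)
  gap <- rep(FALSE, n)
  # alternate 10-sample gaps with 6-sample good runs, avoiding the critical
  # windows around trial start, stimulus onset, and trial end
  idx <- which((tr$t_ms > 150 & tr$t_ms < 790) |
                 (tr$t_ms > 990 & tr$t_ms < 1225))
  gap[idx[(seq_along(idx) - 1) %% 16 < 10]] <- TRUE
  tr$gaze_x_deg[gap] <- NA
  expect_gt(mean(gap), 0.30)  # fixture sanity
  cl <- clean_traces(as_session(tr, spec), GEOM)
  expect_false(cl$trials$valid)
  expect_equal(cl$trials$reason, "missing_samples")
})

test_that("non-monotone timestamps raise an error", {
  spec <- make_spec()
  tr <- flat_trace(spec)
  tr$t_ms[10] <- tr$t_ms[12]
  expect_error(clean_traces(as_session(tr, spec), GEOM), "timestamps")
})

test_that("gaze glued to the stimulus gives 100% tracking and zero GSD", {
  spec <- make_spec(fixation = 390, flight = 585, jitter = 0)
  sp <- as.list(spec[1, ])
  tr <- flat_trace(spec)
  fl <- tr$t_ms >= 390
  stim <- stimulus_position(sp, GEOM, pmin(tr$t_ms[fl] - 390, 585))
  tr$gaze_x_deg[fl] <- stim[, 1]
  tr$gaze_y_deg[fl] <- stim[, 2]
  eo <- extract_eye_outcomes(tr, spec, GEOM)
  expect_equal(eo$tracking_pct, 100)
  expect_equal(eo$mean_gsd_deg, 0, tolerance = 1e-9)
  expect_equal(eo$total_tracking_ms, 5 * sum(fl))
})

test_that("stationary gaze tracks only while the stimulus is nearby", {
  # gaze stays on the fixation cross; oracle: count path samples within 8 deg
  spec <- make_spec(fixation = 390, flight = 585, jitter = 0, location = 1L)
  sp <- as.list(spec[1, ])
  tr <- flat_trace(spec)  # gaze at fixation throughout
  eo <- extract_eye_outcomes(tr, spec, GEOM)
  fl_t <- tr$t_ms[tr$t_ms >= 390] - 390
  stim <- stimulus_position(sp, GEOM, pmin(fl_t, 585))
  d <- sqrt((stim[, 1] - GEOM$fixation_pos[1])^2 +
              (stim[, 2] - GEOM$fixation_pos[2])^2)
  expect_equal(eo$total_tracking_ms, 5 * sum(d < 8))
  expect_lt(eo$tracking_pct, 100)
  expect_true(is.na(eo$eye_response_time_ms))
  expect_equal(eo$eye_reason, "no saccade")
  expect_equal(eo$fixation_error_deg, 0)
})

test_that("noise-free saccades are recovered at the generator's parameters", {
  p <- quiet_profile(saccade_latency_mean_ms = 200)
  spec <- make_spec(fixation = 890, flight = 985, jitter = 0, probe = TRUE)
  fx <- trial_trace(p, spec, seed = 3)
  eo <- extract_eye_outcomes(fx$trace, spec, GEOM)
  expect_equal(eo$eye_response_time_ms, 200, tolerance = 5 / 200)
  truth_amp <- fx$truth$saccade_amplitude_deg
  expect_equal(eo$primary_saccade_amplitude_deg, truth_amp,
               tolerance = 0.5 / truth_amp)
})

test_that("raising the velocity threshold never decreases eye response time", {
  p <- quiet_profile()
  spec <- make_spec(fixation = 390, flight = 585)
  fx <- trial_trace(p, spec, seed = 8)
  erts <- sapply(c(30, 50, 80, 120, 200), function(thr) {
    eo <- extract_eye_outcomes(fx$trace, spec, GEOM,
                               det = detector_config(saccade_vel_deg_s = thr))
    eo$eye_response_time_ms
  })
  expect_true(all(diff(erts) >= 0))
})

test_that("hand outcomes follow the 20 deg/s first-crossing definition", {
  spec <- make_spec(fixation = 890, flight = 485, jitter = 0)
  # no-touch trial: fields absent with reason
  tr <- flat_trace(spec, hand = 5)
  ho <- extract_hand_outcomes(tr, spec)
  expect_true(is.na(ho$hand_response_time_ms))
  expect_true(is.na(ho$touch_time_ms))
  expect_equal(ho$hand_reason, "no touch")

  # permanently sub-threshold speed: onset absent
  tr2 <- flat_trace(spec, hand = 19.9)
  tr2$touched <- TRUE
  tr2$touch_time_ms <- 890 + 400
  ho2 <- extract_hand_outcomes(tr2, spec)
  expect_true(is.na(ho2$hand_response_time_ms))
  expect_equal(ho2$hand_reason, "no movement onset")

  # simulated movement: rt 350, touch 440 (rt + 90 ms movement)
  p <- quiet_profile(hand_rt_mean_ms = 350, criterion = -100)
  fx <- trial_trace(p, spec, seed = 2)
  ho3 <- extract_hand_outcomes(fx$trace, spec)
  expect_equal(ho3$hand_response_time_ms, 350, tolerance = 5 / 350)
  expect_equal(ho3$touch_time_ms, 440, tolerance = 5 / 440)

  # touch before movement onset is flagged
  tr3 <- flat_trace(spec, hand = 0)
  n <- nrow(tr3)
  tr3$hand_speed_deg_s[tr3$t_ms > 1200] <- 100
  tr3$touched <- TRUE
  tr3$touch_time_ms <- 890 + 100
  ho4 <- extract_hand_outcomes(tr3, spec)
  expect_equal(ho4$hand_reason, "inconsistent kinematics")
})

test_that("tracking conservation and GSD bound hold on simulated sessions", {
  p <- subject_profile("control")
  sch <- generate_tpt_block(GEOM, seed = 31)
  sess <- simulate_session(p, sch, GEOM, seed = 31)
  out <- extract_outcomes(clean_traces(sess, GEOM), GEOM)
  ok <- out$valid
  expect_true(all(out$tracking_pct[ok] >= 0 & out$tracking_pct[ok] <= 100))
  flight_eff <- out$flight_duration_ms + out$jitter_ms
  n_fl <- flight_eff / 5 + 1
  expect_true(all(abs(out$total_tracking_ms[ok] / (5 * n_fl[ok]) * 100 -
                        out$tracking_pct[ok]) < 1e-9))
  expect_true(all(out$mean_gsd_deg[ok & !is.na(out$mean_gsd_deg)] < 8))
})

test_that("the reliability gate requires ten valid trials per parameter", {
  base <- tibble::tibble(
    subject = rep(c("a", "b", "c"), times = c(9, 10, 0)),
    latency_to_peak_ms = c(rnorm(19))
  )
  base <- dplyr::bind_rows(base, tibble::tibble(subject = "c",
                                                latency_to_peak_ms = NA_real_))
  gate <- reliability_gate(base, parameters = "latency_to_peak_ms")
  expect_false(gate$included[gate$subject == "a"])
  expect_true(gate$included[gate$subject == "b"])
  expect_false(gate$included[gate$subject == "c"])
  expect_equal(gate$n_valid[gate$subject == "c"], 0L)
})
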