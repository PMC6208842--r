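# Shared fixtures: all built in code at test time.

GEOM <- build_geometry()

# A deterministic, noise-free profile for oracle-equivalence tests.
# Pursuit gain 0.5 keeps pursuit velocity below the 50 deg/s saccade
# threshold on every flight speed, so saccade offset detection terminates.
quiet_profile <- function(...) {
  subject_profile(
    "control",
    gaze_noise_sd_deg = 0, fixation_drift_sd_deg_s = 0,
    pupil_noise_sd_mm = 0, blink_rate_per_min = 0,
    saccade_latency_sd_ms = 0, hand_rt_sd_ms = 0,
    pursuit_gain = 0.5, pursuit_lag_ms = 0,
    late_touch_prob = 0,
    ...
  )
}

# One trial spec without going through the schedule generator.
make_spec <- function(fixation = 890, flight = 485, jitter = 0,
                      location = 2L, probe = FALSE, id = "t001",
                      block = 1L) {
  tibble::tibble(
    trial_id = id, block = block,
    fixation_duration_ms = fixation, flight_duration_ms = flight,
    jitter_ms = jitter, final_location_index = location,
    is_go = GEOM$final_locations$is_go[location], is_probe = probe,
    feedback_duration_ms = 500
  )
}

# Simulate a single trial into the long trace format used by extractors.
trial_trace <- function(profile, spec, seed = 1) {
  sched <- spec
  sess <- simulate_session(profile, sched, GEOM, seed = seed)
  list(trace = sess$traces, truth = sess$truth, spec = spec)
}

# A synthetic flat trace with explicit channels, for handcrafted cases.
flat_trace <- function(spec, gaze_x = NULL, gaze_y = NULL, pupil = 3,
                       hand = 0) {
  total <- spec$fixation_duration_ms + spec$flight_duration_ms + spec$jitter_ms
  t <- seq(0, total, by = 5)
  n <- length(t)
  tibble::tibble(
    subject = "s01", block = 1L, trial_id = spec$trial_id, t_ms = t,
    gaze_x_deg = if (is.null(gaze_x)) rep(GEOM$fixation_pos[1], n)
                 else rep_len(gaze_x, n),
    gaze_y_deg = if (is.null(gaze_y)) rep(GEOM$fixation_pos[2], n)
                 else rep_len(gaze_y, n),
    pupil_mm = rep_len(pupil, n),
    hand_speed_deg_s = rep_len(hand, n),
    blink = FALSE, touched = FALSE, touch_time_ms = NA_real_,
    touch_x_deg = NA_real_, touch_y_deg = NA_real_
  )
}

as_session <- function(trace, spec) {
  list(traces = trace, schedule = spec, subject = trace$subject[1])
}
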