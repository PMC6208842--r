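# Synthetic-subject simulator: go/no-go choices plus 200 Hz gaze, pupil and
# hand traces with known ground truth. All simulate_* functions consume the
# current RNG stream; simulate_session() seeds it.

trial_times <- function(spec) {
  total <- spec$fixation_duration_ms + spec$flight_duration_ms + spec$jitter_ms
  seq(0, total, by = SAMPLE_MS)
}

#' Simulate the go/no-go decision of one trial
#'
#' Equal-variance signal-detection model: evidence `e ~ N(d' * is_go, 1)` is
#' drawn and the subject intends to touch iff `e > c`. If a touch is
#' intended, a hand reaction time and planned touch time are drawn; with a
#' small probability (`late_touch_prob`) the touch is planned after flight
#' end, producing a miss by lateness rather than by choice.
#'
#' @param profile a [subject_profile()].
#' @param spec one schedule row.
#' @return list with `touched`, `evidence`, `dprime_used`, `hand_rt_ms`
#'   and `planned_touch_ms` (both relative to stimulus onset; `NA` when no
#'   touch is intended).
#' @export
simulate_decision <- function(profile, spec) {
  d <- profile_dprime(profile, spec$flight_duration_ms)
  e <- rnorm(1, mean = d * as.numeric(spec$is_go), sd = 1)
  touched <- e > profile$criterion
  hand_rt <- NA_real_; planned <- NA_real_
  if (touched) {
    flight_eff <- spec$flight_duration_ms + spec$jitter_ms
    hand_rt <- max(100, rnorm(1, profile$hand_rt_mean_ms, profile$hand_rt_sd_ms))
    planned <- hand_rt + profile$hand_movement_ms
    if (runif(1) < profile$late_touch_prob) {
      planned <- flight_eff + 50 + rexp(1, rate = 1 / 100)
      hand_rt <- planned - profile$hand_movement_ms
    }
  }
  list(touched = touched, evidence = e, dprime_used = d,
       hand_rt_ms = hand_rt, planned_touch_ms = planned)
}

#' Simulate the gaze trace of one trial
#'
#' During fixation, gaze sits on the fixation cross plus white noise and a
#' slow random-walk drift. After a drawn saccadic latency, a minimum-jerk
#' saccade (duration 21 + 2.2 ms/deg of amplitude, peak velocity well above
#' the 50 deg/s detection threshold) lands on the stimulus trajectory, after
#' which gaze pursues the stimulus with the profile's lag and gain.
#'
#' @param profile a [subject_profile()].
#' @param spec one schedule row.
#' @param geometry a [build_geometry()] object.
#' @return list: `t_ms`, `x`, `y` (equal-length sample vectors) and `truth`
#'   (saccade latency in ms after stimulus onset, amplitude in deg; `NA` if
#'   the latency draw exceeded the flight).
#' @export
simulate_gaze_trial <- function(profile, spec, geometry) {
  t <- trial_times(spec)
  n <- length(t)
  onset <- spec$fixation_duration_ms
  flight_eff <- spec$flight_duration_ms + spec$jitter_ms
  fix <- geometry$fixation_pos
  stim_at <- function(s) {
    stimulus_position(spec, geometry, pmin(pmax(s, 0), flight_eff))
  }

  latency <- max(0, rnorm(1, profile$saccade_latency_mean_ms,
                          profile$saccade_latency_sd_ms))
  t_on <- onset + latency

  x <- rep(fix[1], n); y <- rep(fix[2], n)
  # fixation drift: random walk frozen at stimulus onset
  pre <- t < t_on
  n_pre <- sum(pre)
  step_sd <- profile$fixation_drift_sd_deg_s * sqrt(SAMPLE_MS / 1000)
  if (n_pre > 0 && step_sd > 0) {
    x[pre] <- x[pre] + cumsum(rnorm(n_pre, 0, step_sd))
    y[pre] <- y[pre] + cumsum(rnorm(n_pre, 0, step_sd))
  }

  truth_lat <- NA_real_; truth_amp <- NA_real_
  if (t_on < onset + flight_eff) {
    a0 <- as.numeric(euclid(fix[1], fix[2],
                            stim_at(t_on - onset)[, 1], stim_at(t_on - onset)[, 2]))
    dur <- (21 + 2.2 * a0) / profile$saccade_vel_scale
    t_land <- min(t_on + dur, onset + flight_eff)
    target <- stim_at(t_land - onset - profile$pursuit_lag_ms)
    sacc <- t >= t_on & t <= t_land
    tau <- (t[sacc] - t_on) / dur
    x[sacc] <- fix[1] + (target[, 1] - fix[1]) * min_jerk(tau)
    y[sacc] <- fix[2] + (target[, 2] - fix[2]) * min_jerk(tau)
    post <- t > t_land
    if (any(post)) {
      s_now <- stim_at(t[post] - onset - profile$pursuit_lag_ms)
      s_ref <- stim_at(t_land - onset - profile$pursuit_lag_ms)
      x[post] <- target[, 1] + profile$pursuit_gain * (s_now[, 1] - s_ref[, 1])
      y[post] <- target[, 2] + profile$pursuit_gain * (s_now[, 2] - s_ref[, 2])
    }
    truth_lat <- latency
    truth_amp <- as.numeric(euclid(fix[1], fix[2], target[, 1], target[, 2]))
  }

  if (profile$gaze_noise_sd_deg > 0) {
    x <- x + rnorm(n, 0, profile$gaze_noise_sd_deg)
    y <- y + rnorm(n, 0, profile$gaze_noise_sd_deg)
  }
  list(t_ms = t, x = x, y = y,
       truth = list(saccade_latency_ms = truth_lat,
                    saccade_amplitude_deg = truth_amp))
}

# Unimodal Erlang-style dilation kernel, normalized to peak 1 at t = tp.
pupil_kernel <- function(t_ms, tp_ms, shape) {
  z <- pmax(t_ms, 0) / tp_ms
  (z^shape) * exp(shape * (1 - z))
}

#' Simulate the pupil trace of one trial
#'
#' Diameter = baseline + a linear ramp over the fixation period (held
#' constant afterwards) + a smooth unimodal task-evoked dilation locked to
#' stimulus onset and peaking at the profile's latency-to-peak for the
#' trial's (fixation, speed) condition + white measurement noise. The
#' latency-to-peak parameter is expressed from trial (fixation) onset and
#' must exceed the fixation duration. Diameter stays positive.
#'
#' @inheritParams simulate_decision
#' @return list: `t_ms`, `pupil_mm`, and `truth` (latency to peak from trial
#'   onset, fixation ramp slope mm/s, baseline mm, amplitude mm).
#' @export
simulate_pupil_trial <- function(profile, spec) {
  t <- trial_times(spec)
  onset <- spec$fixation_duration_ms
  tp <- profile_pupil_latency(profile, spec)
  tp_rel <- max(tp - onset, 10 * SAMPLE_MS)  # peak time after stimulus onset
  ramp <- profile$pupil_fixation_slope_mm_s * pmin(t, onset) / 1000
  evoked <- profile$pupil_amplitude_mm *
    pupil_kernel(t - onset, tp_rel, profile$pupil_kernel_shape)
  d <- profile$pupil_baseline_mm + ramp + evoked
  if (profile$pupil_noise_sd_mm > 0)
    d <- d + rnorm(length(t), 0, profile$pupil_noise_sd_mm)
  d <- pmax(d, 0.1)
  list(t_ms = t, pupil_mm = d,
       truth = list(pupil_latency_to_peak_ms = tp,
                    pupil_fixation_slope_mm_s = profile$pupil_fixation_slope_mm_s,
                    pupil_baseline_mm = profile$pupil_baseline_mm,
                    pupil_amplitude_mm = profile$pupil_amplitude_mm))
}

#' Simulate the hand-speed trace and touch event of one trial
#'
#' On no-touch trials hand speed is sub-threshold noise (strictly below the
#' 20 deg/s detection threshold). On touch trials, speed stays sub-threshold
#' until the hand reaction time, then follows a bell-shaped burst whose
#' first threshold crossing coincides with the reaction time and whose peak
#' (about 148 deg/s) is far above threshold; the touch lands at the planned
#' time on the trial's final location plus aiming error.
#'
#' @inheritParams simulate_decision
#' @param geometry a [build_geometry()] object.
#' @param decision output of [simulate_decision()].
#' @return list: `t_ms`, `hand_speed` (deg/s), `touch` (NULL or list with
#'   `time_ms` absolute from trial onset, `x`, `y`), and `truth`.
#' @export
simulate_hand_trial <- function(profile, spec, geometry, decision) {
  t <- trial_times(spec)
  n <- length(t)
  onset <- spec$fixation_duration_ms
  speed <- pmin(abs(rnorm(n, 0, 4)), 18)
  touch <- NULL
  if (isTRUE(decision$touched)) {
    rt_abs <- onset + decision$hand_rt_ms
    touch_abs <- onset + decision$planned_touch_ms
    mid <- (rt_abs + touch_abs) / 2
    w <- (touch_abs - rt_abs) / 4
    # peak 20*exp(2): the 20 deg/s crossing falls exactly at the reaction time
    bell <- 20 * exp(2) * exp(-0.5 * ((t - mid) / w)^2)
    speed <- pmax(speed, bell)
    loc <- geometry$final_locations[spec$final_location_index, ]
    touch <- list(time_ms = touch_abs,
                  x = loc$x + rnorm(1, 0, profile$touch_error_sd_deg),
                  y = loc$y + rnorm(1, 0, profile$touch_error_sd_deg))
  }
  list(t_ms = t, hand_speed = speed, touch = touch,
       truth = list(hand_rt_ms = decision$hand_rt_ms,
                    planned_touch_ms = decision$planned_touch_ms))
}

# One full trial: decision + three channels + blinks. Returns plain vectors
# (hot path); simulate_session() assembles the tibbles.
simulate_trial <- function(profile, spec, geometry) {
  dec <- simulate_decision(profile, spec)
  gz <- simulate_gaze_trial(profile, spec, geometry)
  pu <- simulate_pupil_trial(profile, spec)
  hd <- simulate_hand_trial(profile, spec, geometry, dec)

  t <- gz$t_ms; n <- length(t)
  blink <- rep(FALSE, n)
  total <- t[n]
  n_blinks <- rpois(1, profile$blink_rate_per_min * total / 60000)
  if (n_blinks > 0) {
    onsets <- runif(n_blinks, 0, total)
    for (b in onsets)
      blink <- blink | (t >= b & t < b + profile$blink_duration_ms)
  }
  x <- gz$x; y <- gz$y; p <- pu$pupil_mm
  x[blink] <- NA_real_; y[blink] <- NA_real_; p[blink] <- NA_real_

  list(
    t_ms = t, gaze_x_deg = x, gaze_y_deg = y, pupil_mm = p,
    hand_speed_deg_s = hd$hand_speed, blink = blink,
    touched = isTRUE(dec$touched),
    touch_time_ms = if (is.null(hd$touch)) NA_real_ else hd$touch$time_ms,
    touch_x_deg = if (is.null(hd$touch)) NA_real_ else hd$touch$x,
    touch_y_deg = if (is.null(hd$touch)) NA_real_ else hd$touch$y,
    truth = c(list(is_go = spec$is_go, evidence = dec$evidence,
                   dprime_used = dec$dprime_used, touched = dec$touched),
              hd$truth, gz$truth, pu$truth)
  )
}

#' Simulate a complete session
#'
#' Runs the full generative model over a schedule: a signal-detection
#' decision, gaze/pupil/hand traces at 200 Hz, blinks, and touch events,
#' all deterministic given the seed. Both the observable traces and the
#' hidden ground truth are returned so that downstream extraction can be
#' checked against the generator.
#'
#' @param profile a [subject_profile()].
#' @param schedule a schedule from [generate_tpt_schedule()].
#' @param geometry a [build_geometry()] object.
#' @param seed integer seed.
#' @param subject subject identifier stored in the trace table.
#' @return An object of class `session_traces`: list with `traces` (long
#'   tibble: subject, block, trial_id, t_ms, gaze_x_deg, gaze_y_deg,
#'   pupil_mm, hand_speed_deg_s, blink, touched, touch_time_ms,
#'   touch_x_deg, touch_y_deg), `truth` (one row per trial), `schedule`,
#'   `subject`.
#' @export
simulate_session <- function(profile, schedule, geometry, seed,
                             subject = "s01") {
  stopifnot(inherits(profile, "subject_profile"))
  trials <- withr::with_seed(seed, {
    lapply(seq_len(nrow(schedule)), function(i) {
      simulate_trial(profile, as.list(schedule[i, ]), geometry)
    })
  })
  ns <- vapply(trials, function(tr) length(tr$t_ms), integer(1))
  per_trial <- function(field) rep(vapply(trials, function(tr) tr[[field]],
                                          numeric(1)), ns)
  traces <- tibble::tibble(
    subject = subject,
    block = rep(schedule$block, ns),
    trial_id = rep(schedule$trial_id, ns),
    t_ms = unlist(lapply(trials, `[[`, "t_ms")),
    gaze_x_deg = unlist(lapply(trials, `[[`, "gaze_x_deg")),
    gaze_y_deg = unlist(lapply(trials, `[[`, "gaze_y_deg")),
    pupil_mm = unlist(lapply(trials, `[[`, "pupil_mm")),
    hand_speed_deg_s = unlist(lapply(trials, `[[`, "hand_speed_deg_s")),
    blink = unlist(lapply(trials, `[[`, "blink")),
    touched = rep(vapply(trials, `[[`, logical(1), "touched"), ns),
    touch_time_ms = per_trial("touch_time_ms"),
    touch_x_deg = per_trial("touch_x_deg"),
    touch_y_deg = per_trial("touch_y_deg")
  )
  truth <- dplyr::bind_rows(lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]$truth
    tibble::tibble(
      subject = subject, trial_id = schedule$trial_id[i],
      block = schedule$block[i], is_go = tr$is_go,
      evidence = tr$evidence, dprime_used = tr$dprime_used,
      touched = tr$touched, hand_rt_ms = tr$hand_rt_ms,
      planned_touch_ms = tr$planned_touch_ms,
      saccade_latency_ms = tr$saccade_latency_ms,
      saccade_amplitude_deg = tr$saccade_amplitude_deg,
      pupil_latency_to_peak_ms = tr$pupil_latency_to_peak_ms,
      pupil_fixation_slope_mm_s = tr$pupil_fixation_slope_mm_s,
      pupil_baseline_mm = tr$pupil_baseline_mm,
      pupil_amplitude_mm = tr$pupil_amplitude_mm
    )
  }))
  structure(list(traces = traces, truth = truth, schedule = schedule,
                 subject = subject, seed = seed),
            class = "session_traces")
}

#' @export
print.session_traces <- function(x, ...) {
  cat("<session_traces>", x$subject, "-", nrow(x$schedule), "trials,",
      nrow(x$traces), "samples at 200 Hz\n")
  invisible(x)
}

#' Simulate key presses for the simple reaction-time task
#'
#' Draws normal reaction times around the profile's mean, with small
#' probabilities of an anticipatory press (landing in the catch window) and
#' of a lapse (exceeding the maximum allowed reaction time).
#'
#' @param profile a [subject_profile()].
#' @param schedule an [generate_rtt_schedule()] schedule.
#' @param seed integer seed.
#' @param anticipation_prob,lapse_prob mixture weights for catch/lapse trials.
#' @return tibble with `trial` and `press_ms` (time of key press after
#'   stimulus onset).
#' @export
simulate_rtt_session <- function(profile, schedule, seed,
                                 anticipation_prob = 0.02,
                                 lapse_prob = 0.02) {
  n <- nrow(schedule)
  withr::with_seed(seed, {
    rt <- rnorm(n, profile$rtt_rt_mean_ms, profile$rtt_rt_sd_ms)
    u <- runif(n)
    rt[u < anticipation_prob] <- runif(sum(u < anticipation_prob), 50, 124)
    lapse <- u >= anticipation_prob & u < anticipation_prob + lapse_prob
    rt[lapse] <- runif(sum(lapse), 760, 950)
    tibble::tibble(trial = schedule$trial, press_ms = pmax(rt, 30))
  })
}
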