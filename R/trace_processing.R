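# Trial quality control and extraction of the eye/hand outcome parameters.

#' Quality-control configuration
#'
#' Explicit, automated replacements for manual blind trial rating. A trial is
#' invalidated when (a) a blink or signal gap overlaps a critical window
#' (first 100 ms of the trial, stimulus onset +/- 50 ms, or the last 100 ms),
#' (b) more than 30% of samples remain missing after interpolation, or
#' (c) gaze is off screen in more than 20% of samples. Gaps no longer than
#' `max_interp_ms` outside the critical windows are linearly interpolated.
#'
#' @param max_interp_ms longest gap that may be bridged by interpolation.
#' @param max_missing_frac,max_offscreen_frac rejection thresholds.
#' @param critical_start_ms,onset_pad_ms,critical_end_ms critical-window
#'   sizes in ms.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(max_interp_ms = 200,
                      max_missing_frac = 0.30,
                      max_offscreen_frac = 0.20,
                      critical_start_ms = 100,
                      onset_pad_ms = 50,
                      critical_end_ms = 100) {
  structure(list(max_interp_ms = max_interp_ms,
                 max_missing_frac = max_missing_frac,
                 max_offscreen_frac = max_offscreen_frac,
                 critical_start_ms = critical_start_ms,
                 onset_pad_ms = onset_pad_ms,
                 critical_end_ms = critical_end_ms),
            class = "qc_config")
}

#' Detector thresholds used by the outcome extractors
#'
#' Defaults equal the task's printed analysis constants: saccade onset at
#' gaze velocity exceeding 50 deg/s, tracking defined as gaze within 8 deg
#' of the stimulus, hand movement onset at finger velocity exceeding
#' 20 deg/s, 100 ms pupil analysis windows, and the 125 ms catch / 750 ms
#' maximum reaction-time rules of the simple reaction-time task.
#'
#' @param saccade_vel_deg_s,tracking_dist_deg,hand_vel_deg_s detector
#'   thresholds.
#' @param window_ms pupil window length.
#' @param rtt_catch_ms,rtt_max_rt_ms reaction-time task filter rules.
#' @param smooth_k samples in the moving-average filter applied to gaze
#'   position before differentiation.
#' @param offset_below_n consecutive sub-threshold samples ending a saccade.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(saccade_vel_deg_s = 50,
                            tracking_dist_deg = 8,
                            hand_vel_deg_s = 20,
                            window_ms = 100,
                            rtt_catch_ms = 125,
                            rtt_max_rt_ms = 750,
                            smooth_k = 5L,
                            offset_below_n = 2L) {
  structure(list(saccade_vel_deg_s = saccade_vel_deg_s,
                 tracking_dist_deg = tracking_dist_deg,
                 hand_vel_deg_s = hand_vel_deg_s,
                 window_ms = window_ms,
                 rtt_catch_ms = rtt_catch_ms,
                 rtt_max_rt_ms = rtt_max_rt_ms,
                 smooth_k = smooth_k,
                 offset_below_n = offset_below_n),
            class = "detector_config")
}

#' Angular gaze velocity
#'
#' Central-difference derivative of (optionally smoothed) gaze position,
#' with one-sided differences at the ends; length is preserved. Smoothing is
#' a centered 5-sample (25 ms) moving average by default.
#'
#' @param x,y gaze position in degrees.
#' @param t_ms sample times in ms (defaults to a 5 ms grid).
#' @param smooth_k moving-average window in samples; use `1` for the raw
#'   finite difference.
#' @return numeric vector of speeds in deg/s.
#' @export
#' @examples
#' t <- seq(0, 1000, by = 5)
#' angular_velocity(30 * t / 1000, rep(0, length(t)), t)[10]  # ~30 deg/s
angular_velocity <- function(x, y, t_ms = NULL, smooth_k = 5L) {
  n <- length(x)
  if (n < 3L) stop("angular_velocity needs at least 3 samples", call. = FALSE)
  if (is.null(t_ms)) t_ms <- seq(0, by = SAMPLE_MS, length.out = n)
  xs <- moving_average(x, smooth_k)
  ys <- moving_average(y, smooth_k)
  i <- seq_len(n)
  lo <- pmax(i - 1L, 1L); hi <- pmin(i + 1L, n)
  dt <- (t_ms[hi] - t_ms[lo]) / 1000
  sqrt((xs[hi] - xs[lo])^2 + (ys[hi] - ys[lo])^2) / dt
}

# index ranges of runs of TRUE
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

clean_one_trial <- function(tr, onset, qc, geometry) {
  t <- tr$t_ms
  if (is.unsorted(t, strictly = TRUE))
    stop("non-monotone timestamps in trial", call. = FALSE)
  t_end <- t[length(t)]
  windows <- rbind(c(0, qc$critical_start_ms),
                   c(onset - qc$onset_pad_ms, onset + qc$onset_pad_ms),
                   c(t_end - qc$critical_end_ms, t_end))
  gap <- is.na(tr$gaze_x_deg) | is.na(tr$gaze_y_deg) | is.na(tr$pupil_mm) |
    tr$blink
  reason <- NA_character_
  if (any(gap)) {
    runs <- true_runs(gap)
    for (k in seq_len(nrow(runs))) {
      g0 <- t[runs[k, 1]]; g1 <- t[runs[k, 2]]
      len_ms <- (runs[k, 2] - runs[k, 1] + 1L) * SAMPLE_MS
      if (len_ms > qc$max_interp_ms ||
          any(g1 >= windows[, 1] & g0 <= windows[, 2])) {
        reason <- "blink"
        break
      }
    }
    if (is.na(reason) && mean(gap) > qc$max_missing_frac)
      reason <- "missing_samples"
    if (is.na(reason)) {
      for (k in seq_len(nrow(runs))) {
        idx <- runs[k, 1]:runs[k, 2]
        for (col in c("gaze_x_deg", "gaze_y_deg", "pupil_mm")) {
          v <- tr[[col]]
          v[idx] <- NA_real_
          if (sum(!is.na(v)) >= 2L)
            tr[[col]][idx] <- approx(t[!is.na(v)], v[!is.na(v)],
                                     xout = t[idx], rule = 2)$y
        }
      }
    }
  }
  if (is.na(reason)) {
    off <- abs(tr$gaze_x_deg) > geometry$screen_halfwidth_deg |
      abs(tr$gaze_y_deg) > geometry$screen_halfheight_deg
    if (mean(off, na.rm = TRUE) > qc$max_offscreen_frac) reason <- "offscreen_gaze"
  }
  list(trace = tr, valid = is.na(reason), reason = reason)
}

#' Clean session traces (blink interpolation + trial QC)
#'
#' @param session a `session_traces` object (or a compatible list with
#'   `traces` and `schedule`).
#' @param geometry a [build_geometry()] object.
#' @param qc a [qc_config()].
#' @return list of class `clean_session`: `traces` (interpolated),
#'   `trials` (tibble: `trial_id`, `valid`, `reason`), `schedule`.
#' @export
clean_traces <- function(session, geometry, qc = qc_config()) {
  traces <- session$traces
  schedule <- session$schedule
  onset_by_trial <- setNames(schedule$fixation_duration_ms, schedule$trial_id)
  idx <- split(seq_len(nrow(traces)), traces$trial_id)
  idx <- idx[schedule$trial_id]  # schedule order
  out_traces <- vector("list", length(idx))
  valid <- logical(length(idx)); reason <- character(length(idx))
  for (i in seq_along(idx)) {
    tid <- schedule$trial_id[i]
    res <- clean_one_trial(traces[idx[[i]], ], onset_by_trial[[tid]], qc,
                           geometry)
    out_traces[[i]] <- res$trace
    valid[i] <- res$valid
    reason[i] <- if (is.na(res$reason)) NA_character_ else res$reason
  }
  structure(list(
    traces = dplyr::bind_rows(out_traces),
    trials = tibble::tibble(trial_id = schedule$trial_id, valid = valid,
                            reason = reason),
    schedule = schedule,
    subject = session$subject %||% unique(traces$subject)[1]
  ), class = "clean_session")
}

# first index where v strictly exceeds thr at or after from_idx (NA-safe)
first_crossing <- function(v, thr, from_idx = 1L) {
  ok <- which(!is.na(v) & v > thr & seq_along(v) >= from_idx)
  if (length(ok)) ok[1] else NA_integer_
}

extract_eye_one <- function(tr, spec, geometry, det) {
  t <- tr$t_ms
  onset <- spec$fixation_duration_ms
  flight_eff <- spec$flight_duration_ms + spec$jitter_ms
  v <- angular_velocity(tr$gaze_x_deg, tr$gaze_y_deg, t,
                        smooth_k = det$smooth_k)

  # fixation error over the whole fixation period
  fixsel <- t < onset
  fe <- mean(euclid(tr$gaze_x_deg[fixsel], tr$gaze_y_deg[fixsel],
                    geometry$fixation_pos[1], geometry$fixation_pos[2]),
             na.rm = TRUE)

  # saccade onset: first post-onset velocity-threshold crossing
  post0 <- which(t > onset)[1]
  ert <- NA_real_; amp <- NA_real_; eye_reason <- NA_character_
  ion <- first_crossing(v, det$saccade_vel_deg_s, post0)
  if (is.na(ion)) {
    eye_reason <- "no saccade"
  } else {
    ert <- t[ion] - onset
    below <- !is.na(v) & v < det$saccade_vel_deg_s
    ioff <- NA_integer_
    j <- ion + 1L
    n <- length(v)
    while (j <= n - det$offset_below_n + 1L) {
      if (all(below[j:(j + det$offset_below_n - 1L)])) { ioff <- j; break }
      j <- j + 1L
    }
    if (is.na(ioff)) ioff <- n
    amp <- euclid(tr$gaze_x_deg[ion], tr$gaze_y_deg[ion],
                  tr$gaze_x_deg[ioff], tr$gaze_y_deg[ioff])
  }

  # tracking during flight
  fl <- t >= onset & t <= onset + flight_eff
  stim <- stimulus_position(spec, geometry, t[fl] - onset)
  d <- euclid(tr$gaze_x_deg[fl], tr$gaze_y_deg[fl], stim[, 1], stim[, 2])
  trackn <- sum(!is.na(d) & d < det$tracking_dist_deg)
  n_fl <- sum(fl)
  tibble::tibble(
    total_tracking_ms = trackn * SAMPLE_MS,
    tracking_pct = 100 * trackn / n_fl,
    mean_gsd_deg = if (trackn > 0)
      mean(d[!is.na(d) & d < det$tracking_dist_deg]) else NA_real_,
    eye_response_time_ms = ert,
    primary_saccade_amplitude_deg = amp,
    fixation_error_deg = fe,
    eye_reason = eye_reason
  )
}

extract_hand_one <- function(tr, spec, det) {
  t <- tr$t_ms
  onset <- spec$fixation_duration_ms
  post0 <- which(t > onset)[1]
  ih <- first_crossing(tr$hand_speed_deg_s, det$hand_vel_deg_s, post0)
  hrt <- if (is.na(ih)) NA_real_ else t[ih] - onset
  touched <- isTRUE(tr$touched[1])
  tt <- if (touched && !is.na(tr$touch_time_ms[1]))
    tr$touch_time_ms[1] - onset else NA_real_
  reason <- NA_character_
  if (!touched) reason <- "no touch"
  else if (is.na(hrt)) reason <- "no movement onset"
  else if (!is.na(tt) && tt < hrt) reason <- "inconsistent kinematics"
  tibble::tibble(hand_response_time_ms = hrt, touch_time_ms = tt,
                 hand_reason = reason)
}

#' Extract eye-movement outcomes for one trial
#'
#' Computes, relative to stimulus onset: eye response time (first gaze
#' velocity crossing of 50 deg/s), primary saccade amplitude (gaze
#' displacement from that crossing to the first sustained return below
#' threshold), total tracking time in ms and as percent of flight (samples
#' with gaze within 8 deg of the stimulus), mean gaze-stimulus distance over
#' tracking samples, and the mean fixation error over the fixation period.
#'
#' @param trial_trace samples of one trial (rows of a `clean_session`
#'   trace table).
#' @param spec matching schedule row.
#' @param geometry a [build_geometry()] object.
#' @param det a [detector_config()].
#' @return one-row tibble.
#' @export
extract_eye_outcomes <- function(trial_trace, spec, geometry,
                                 det = detector_config()) {
  extract_eye_one(trial_trace, as.list(spec), geometry, det)
}

#' Extract hand-movement outcomes for one trial
#'
#' Hand response time is the first post-onset crossing of 20 deg/s of the
#' finger speed channel; touch time is the touch event time minus stimulus
#' onset. Both are absent (with a reason) on no-touch trials; a touch
#' preceding the movement onset is flagged as inconsistent kinematics.
#'
#' @inheritParams extract_eye_outcomes
#' @return one-row tibble.
#' @export
extract_hand_outcomes <- function(trial_trace, spec, det = detector_config()) {
  extract_hand_one(trial_trace, as.list(spec), det)
}

#' Extract all per-trial outcomes of a cleaned session
#'
#' Runs the eye, hand, and pupil extractors over every valid trial; invalid
#' trials appear with their rejection reason and all outcome fields missing.
#'
#' @param clean a `clean_session` from [clean_traces()].
#' @param geometry a [build_geometry()] object.
#' @param det a [detector_config()].
#' @return tibble with one row per trial: identifiers, condition columns,
#'   validity, the seven eye/two hand outcomes, and the eight pupil
#'   outcomes.
#' @export
extract_outcomes <- function(clean, geometry, det = detector_config()) {
  stopifnot(inherits(clean, "clean_session"))
  schedule <- clean$schedule
  idx <- split(seq_len(nrow(clean$traces)), clean$traces$trial_id)
  idx <- idx[schedule$trial_id]
  rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    spec <- as.list(schedule[i, ])
    valid <- clean$trials$valid[i]
    tr <- clean$traces[idx[[i]], ]
    base <- tibble::tibble(
      subject = clean$subject, trial_id = spec$trial_id, block = spec$block,
      fixation_duration_ms = spec$fixation_duration_ms,
      flight_duration_ms = spec$flight_duration_ms,
      jitter_ms = spec$jitter_ms,
      final_location_index = spec$final_location_index,
      is_go = spec$is_go, is_probe = spec$is_probe, valid = valid,
      qc_reason = clean$trials$reason[i],
      touched = isTRUE(tr$touched[1]),
      touch_time_abs_ms = tr$touch_time_ms[1]
    )
    if (valid) {
      rows[[i]] <- dplyr::bind_cols(
        base,
        extract_eye_one(tr, spec, geometry, det),
        extract_hand_one(tr, spec, det),
        extract_pupil_one(tr, spec, det)
      )
    } else {
      rows[[i]] <- base
    }
  }
  dplyr::bind_rows(rows)
}

#' Reliability gate: minimum trial counts per outcome parameter
#'
#' A subject's value for an outcome parameter is included only when at least
#' `min_trials` valid trials contribute to it.
#'
#' @param outcomes an [extract_outcomes()] table (possibly several subjects).
#' @param min_trials inclusion threshold (default 10).
#' @param parameters outcome columns to gate; defaults to every numeric
#'   outcome column present.
#' @return tibble: `subject`, `parameter`, `n_valid`, `included`.
#' @export
reliability_gate <- function(outcomes, min_trials = 10L, parameters = NULL) {
  default_params <- c(
    "total_tracking_ms", "tracking_pct", "mean_gsd_deg",
    "eye_response_time_ms", "primary_saccade_amplitude_deg",
    "fixation_error_deg", "hand_response_time_ms", "touch_time_ms",
    "baseline_diam_mm", "end_fixation_diam_mm", "end_stimulus_diam_mm",
    "slope_overall_mm_s", "slope_fixation_mm_s", "slope_flight_mm_s",
    "peak_size_change_mm", "latency_to_peak_ms"
  )
  parameters <- parameters %||% intersect(default_params, names(outcomes))
  out <- lapply(parameters, function(p) {
    outcomes |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(n_valid = sum(!is.na(.data[[p]])), .groups = "drop") |>
      dplyr::mutate(parameter = p, included = .data$n_valid >= min_trials)
  })
  dplyr::bind_rows(out)[, c("subject", "parameter", "n_valid", "included")]
}
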