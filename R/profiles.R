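#' Generative parameters of a simulated subject
#'
#' A `subject_profile` holds every parameter the trace simulator needs:
#' oculomotor (saccade latency and kinematic scaling, pursuit lag/gain,
#' fixation noise and drift, blinks), pupillary (baseline, task-evoked
#' dilation amplitude and per-condition latency to peak, fixation ramp
#' slope), manual (hand reaction time, movement duration, touch accuracy),
#' and decisional (equal-variance signal-detection d-prime per flight speed
#' and a criterion). Two presets are provided: a neutral `"control"` and an
#' `"expert"` shifted in the directions reported for elite players —
#' higher d-prime at every speed, earlier pupil peak at the short fixation
#' for fast/medium speeds, later peak at the long fixation, and smaller
#' fixation drift. The preset d-prime values per speed are
#' control 1.14/1.99/2.25 and expert 1.48/2.19/2.57 (fast/medium/slow).
#'
#' `pupil_latency_to_peak_ms` is a 3 x 3 matrix (rows: fixation 390/890/1900
#' ms; columns: speed 385/485/585 ms) of peak times measured from trial
#' (fixation) onset; probe trials use `pupil_latency_probe_ms`.
#'
#' @param group `"control"`, `"expert"`, or any label when overriding fields.
#' @param ... named overrides of any profile field (see Details in the
#'   vignette); unknown names are an error.
#' @return A list of class `subject_profile`.
#' @export
#' @examples
#' p <- subject_profile("expert", gaze_noise_sd_deg = 0.2)
#' p$dprime
subject_profile <- function(group = c("control", "expert"), ...) {
  group <- match.arg(group)
  lat_offsets <- c(260, 340, 420)  # peak time after stimulus onset, by speed
  base_lat <- outer(TPT_FIXATIONS, lat_offsets, `+`)
  dimnames(base_lat) <- list(fixation = TPT_FIXATIONS, speed = TPT_SPEEDS)

  prof <- list(
    group = group,
    # simple reaction-time task
    rtt_rt_mean_ms = 312, rtt_rt_sd_ms = 40,
    # oculomotor
    saccade_latency_mean_ms = 220, saccade_latency_sd_ms = 20,
    saccade_vel_scale = 1,          # divides saccade duration (scales peak velocity)
    pursuit_lag_ms = 100, pursuit_gain = 0.9,
    gaze_noise_sd_deg = 0.3, fixation_drift_sd_deg_s = 0.5,
    blink_rate_per_min = 4, blink_duration_ms = 150,
    # pupil
    pupil_baseline_mm = 3.5, pupil_amplitude_mm = 0.4,
    pupil_latency_to_peak_ms = base_lat,
    pupil_latency_probe_ms = TPT_PROBE_FIXATION + 420,
    pupil_fixation_slope_mm_s = 0.12,
    pupil_kernel_shape = 10, pupil_noise_sd_mm = 0.02,
    # hand
    hand_rt_mean_ms = 230, hand_rt_sd_ms = 25,
    hand_movement_ms = 90, late_touch_prob = 0.02,
    touch_error_sd_deg = 0.8,
    # decision (fast, medium, slow)
    dprime = c(`385` = 1.14, `485` = 1.99, `585` = 2.25),
    # absolute evidence threshold: touch iff e > criterion. A single
    # threshold across speeds yields a constant false-alarm rate while hit
    # rates fall as d' drops at faster speeds.
    criterion = 1.0
  )

  if (group == "expert") {
    prof$rtt_rt_mean_ms <- 310
    prof$dprime <- c(`385` = 1.48, `485` = 2.19, `585` = 2.57)
    prof$saccade_latency_mean_ms <- 205
    prof$pursuit_gain <- 0.95
    prof$fixation_drift_sd_deg_s <- 0.3
    lat <- prof$pupil_latency_to_peak_ms
    lat["390", c("385", "485")] <- lat["390", c("385", "485")] - 60
    lat["1900", ] <- lat["1900", ] + 80
    prof$pupil_latency_to_peak_ms <- lat
  }

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(prof))
    if (length(bad))
      stop("unknown profile field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    prof[names(dots)] <- dots
  }

  stopifnot(
    prof$saccade_latency_sd_ms >= 0, prof$hand_rt_sd_ms >= 0,
    prof$gaze_noise_sd_deg >= 0, prof$pupil_noise_sd_mm >= 0,
    all(is.finite(prof$dprime)),
    prof$pursuit_gain > 0, prof$pursuit_gain <= 1.2
  )
  structure(prof, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile>", x$group, "- d' (fast/med/slow):",
      paste(x$dprime, collapse = "/"), "; criterion", x$criterion, "\n")
  invisible(x)
}

# d-prime applicable to one trial: per-speed for the three main speeds,
# slow-speed value for probes (probes are excluded from d' analyses anyway).
profile_dprime <- function(profile, flight_ms) {
  key <- as.character(flight_ms)
  if (key %in% names(profile$dprime)) unname(profile$dprime[key])
  else unname(profile$dprime[length(profile$dprime)])
}

profile_pupil_latency <- function(profile, spec) {
  if (isTRUE(spec$is_probe)) return(profile$pupil_latency_probe_ms)
  lat <- profile$pupil_latency_to_peak_ms
  fk <- as.character(spec$fixation_duration_ms)
  sk <- as.character(spec$flight_duration_ms)
  if (fk %in% rownames(lat) && sk %in% colnames(lat)) return(lat[fk, sk])
  # off-design condition: anchor to fixation end plus the mean speed offset
  spec$fixation_duration_ms + mean(lat[1, ] - TPT_FIXATIONS[1])
}
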