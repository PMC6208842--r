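# Task-evoked pupillary response outcomes.

#' OLS slope of a pupil-diameter segment
#'
#' Ordinary least-squares slope of diameter against time over a window,
#' returned in mm/s. Invariant to adding a constant to all diameters and
#' antisymmetric under time reversal of the window.
#'
#' @param t_ms sample times (ms).
#' @param pupil_mm diameters (mm).
#' @param window numeric length-2 `[t0, t1]`; defaults to the full series.
#' @return slope in mm/s, or `NA` with fewer than 2 usable samples.
#' @export
#' @examples
#' segment_slope(c(0, 500), c(3.0, 3.2))  # 0.4 mm/s
segment_slope <- function(t_ms, pupil_mm, window = range(t_ms)) {
  sel <- t_ms >= window[1] & t_ms <= window[2]
  ols_slope_per_s(t_ms[sel], pupil_mm[sel])
}

extract_pupil_one <- function(tr, spec, det = detector_config(),
                              min_window_samples = 10L) {
  t <- tr$t_ms
  p <- tr$pupil_mm
  onset <- spec$fixation_duration_ms
  t_end <- t[length(t)]  # end of stimulus presentation (feedback excluded)
  w <- det$window_ms

  if (all(is.na(p))) {
    return(tibble::tibble(
      baseline_diam_mm = NA_real_, end_fixation_diam_mm = NA_real_,
      end_stimulus_diam_mm = NA_real_, slope_overall_mm_s = NA_real_,
      slope_fixation_mm_s = NA_real_, slope_flight_mm_s = NA_real_,
      peak_size_change_mm = NA_real_, latency_to_peak_ms = NA_real_,
      latency_to_peak_from_onset_ms = NA_real_,
      pupil_reason = "no pupil signal"
    ))
  }

  win_mean <- function(t0, t1) {
    v <- p[t >= t0 & t <= t1]
    if (sum(!is.na(v)) < min_window_samples) NA_real_ else mean(v, na.rm = TRUE)
  }
  baseline <- win_mean(0, w)
  end_fix <- win_mean(onset - w, onset)
  end_stim <- win_mean(t_end - w, t_end)

  imax <- which.max(p)  # NAs never win; earliest index on exact ties
  latency <- t[imax]
  peak_change <- if (is.na(baseline)) NA_real_ else p[imax] - baseline

  tibble::tibble(
    baseline_diam_mm = baseline,
    end_fixation_diam_mm = end_fix,
    end_stimulus_diam_mm = end_stim,
    slope_overall_mm_s = segment_slope(t, p, c(0, t_end)),
    slope_fixation_mm_s = segment_slope(t, p, c(0, onset)),
    slope_flight_mm_s = segment_slope(t, p, c(onset, t_end)),
    peak_size_change_mm = peak_change,
    latency_to_peak_ms = latency,
    latency_to_peak_from_onset_ms = latency - onset,
    pupil_reason = NA_character_
  )
}

#' Extract the eight pupillary outcomes of one trial
#'
#' Window means of pupil diameter at baseline (first 100 ms of the trial),
#' end of fixation (last 100 ms of the fixation period), and end of
#' stimulus presentation (last 100 ms); OLS slopes over the whole trial,
#' the fixation period, and the flight; peak size change (trial maximum
#' minus baseline mean) and latency to peak. The trial clock starts at
#' fixation onset; an auxiliary latency relative to stimulus onset is also
#' returned. A window mean is reported only when at least 10 samples
#' contribute.
#'
#' @param trial_trace samples of one trial.
#' @param spec matching schedule row.
#' @param det a [detector_config()] (supplies the 100 ms window length).
#' @param min_window_samples minimum usable samples per window mean.
#' @return one-row tibble with the eight outcomes plus
#'   `latency_to_peak_from_onset_ms` and `pupil_reason`.
#' @export
extract_pupil_outcomes <- function(trial_trace, spec,
                                   det = detector_config(),
                                   min_window_samples = 10L) {
  extract_pupil_one(trial_trace, as.list(spec), det, min_window_samples)
}
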