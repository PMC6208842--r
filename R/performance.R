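# Trial classification, condition summaries, and signal-detection analysis.

#' Classify go/no-go responses
#'
#' A touch that lands before the stimulus reaches its final position on a
#' go trial is a hit; a go trial with no touch, or a touch after flight end,
#' is a miss. A no-go trial without a touch is a correct rejection and with
#' a touch a false alarm. For real recordings, a touch released before
#' flight end (`held = FALSE`) demotes a hit to a miss.
#'
#' @param is_go logical vector.
#' @param touched logical vector.
#' @param touch_time_ms touch time relative to stimulus onset (`NA` when no
#'   touch occurred).
#' @param flight_end_ms effective flight duration per trial.
#' @param held optional logical: was the touch held through flight end?
#' @return factor with levels hit, miss, correct_rejection, false_alarm.
#' @export
classify_response <- function(is_go, touched, touch_time_ms, flight_end_ms,
                              held = TRUE) {
  if (any(!touched & !is.na(touch_time_ms)))
    stop("touch_time_ms present on trials with touched = FALSE", call. = FALSE)
  held <- rep_len(held, length(is_go))
  timely <- touched & !is.na(touch_time_ms) &
    touch_time_ms <= flight_end_ms & held
  out <- ifelse(is_go,
                ifelse(timely, "hit", "miss"),
                ifelse(touched, "false_alarm", "correct_rejection"))
  factor(out, levels = c("hit", "miss", "correct_rejection", "false_alarm"))
}

#' Build response records from outcomes or schedule + touches
#'
#' @param outcomes an [extract_outcomes()] table (uses `touched` and the
#'   touch time relative to onset), or any tibble with the needed columns.
#' @return the input with `response_type` and `correct` columns appended.
#' @export
classify_trials <- function(outcomes) {
  flight_eff <- outcomes$flight_duration_ms +
    (outcomes$jitter_ms %||% 0)
  tt <- if ("touch_time_abs_ms" %in% names(outcomes))
    outcomes$touch_time_abs_ms - outcomes$fixation_duration_ms
  else outcomes$touch_time_ms
  tt[!outcomes$touched] <- NA_real_
  rt <- classify_response(outcomes$is_go, outcomes$touched, tt, flight_eff)
  dplyr::mutate(outcomes, response_type = rt,
                correct = rt %in% c("hit", "correct_rejection"))
}

#' Signal-detection sensitivity and criterion
#'
#' `d' = z(H) - z(F)` with `z` the standard normal quantile and
#' `c = -(z(H) + z(F)) / 2`. Extreme rates (exactly 0 or 1) are adjusted
#' before the transform: `"loglinear"` replaces the rate by
#' `(rate * n + 0.5) / (n + 1)`; `"clamp"` replaces 0 by `1/(2n)` and 1 by
#' `1 - 1/(2n)`; `"none"` leaves them (yielding infinite d').
#'
#' @param hit_rate,fa_rate observed proportions.
#' @param n_go,n_nogo trial counts behind the rates (must be positive).
#' @param correction `"loglinear"` (default), `"clamp"`, or `"none"`.
#' @return list of class `sdt_result`: raw and adjusted rates, `dprime`,
#'   `criterion`, `correction_applied`, `n_go`, `n_nogo`.
#' @export
#' @examples
#' dprime(0.841345, 0.158655, 100, 100)$dprime  # ~2
dprime <- function(hit_rate, fa_rate, n_go, n_nogo,
                   correction = c("loglinear", "clamp", "none")) {
  correction <- match.arg(correction)
  if (n_go <= 0 || n_nogo <= 0)
    stop("d' undefined: need at least one go and one no-go trial", call. = FALSE)
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  adjust <- function(r, n) {
    if (r > 0 && r < 1) return(r)
    switch(correction,
           loglinear = (r * n + 0.5) / (n + 1),
           clamp = if (r == 0) 1 / (2 * n) else 1 - 1 / (2 * n),
           none = r)
  }
  h_adj <- adjust(hit_rate, n_go)
  f_adj <- adjust(fa_rate, n_nogo)
  applied <- (h_adj != hit_rate) || (f_adj != fa_rate)
  zh <- qnorm(h_adj); zf <- qnorm(f_adj)
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 hit_rate_adj = h_adj, fa_rate_adj = f_adj,
                 dprime = zh - zf, criterion = -(zh + zf) / 2,
                 correction = correction, correction_applied = applied,
                 n_go = n_go, n_nogo = n_nogo),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("<sdt_result> H=%.3f F=%.3f d'=%.3f c=%.3f (n_go=%d, n_nogo=%d%s)\n",
              x$hit_rate, x$fa_rate, x$dprime, x$criterion, x$n_go, x$n_nogo,
              if (x$correction_applied) paste0(", ", x$correction, " correction")
              else ""))
  invisible(x)
}

#' d-prime per condition from classified records
#'
#' @param records a [classify_trials()] table.
#' @param by grouping column (default `"flight_duration_ms"`).
#' @param correction passed to [dprime()].
#' @param include_probes include 985 ms probe trials (default FALSE).
#' @return tibble: grouping value, counts, hit/FA rates, `dprime`,
#'   `criterion`.
#' @export
dprime_by_condition <- function(records, by = "flight_duration_ms",
                                correction = "loglinear",
                                include_probes = FALSE) {
  if (!include_probes && "is_probe" %in% names(records))
    records <- records[!records$is_probe, ]
  records |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::group_modify(function(g, key) {
      n_go <- sum(g$is_go); n_nogo <- sum(!g$is_go)
      if (n_go == 0 || n_nogo == 0)
        return(tibble::tibble(n_go = n_go, n_nogo = n_nogo,
                              hit_rate = NA_real_, fa_rate = NA_real_,
                              dprime = NA_real_, criterion = NA_real_))
      h <- sum(g$response_type == "hit") / n_go
      f <- sum(g$response_type == "false_alarm") / n_nogo
      r <- dprime(h, f, n_go, n_nogo, correction)
      tibble::tibble(n_go = n_go, n_nogo = n_nogo, hit_rate = h, fa_rate = f,
                     dprime = r$dprime, criterion = r$criterion)
    }) |>
    dplyr::ungroup()
}

#' Condition-wise performance summary
#'
#' Percent correct per block, per flight speed, per fixation duration, and
#' per speed x fixation cell, plus hit/miss/CR/FA rates per speed with the
#' standard denominators (hits and misses over go trials, CRs and FAs over
#' no-go trials). Probe trials are excluded by default.
#'
#' @param records a [classify_trials()] table (one or more subjects).
#' @param include_probes include 985 ms probe trials (default FALSE).
#' @return list of class `condition_summary` with tibbles `overall`,
#'   `by_block`, `by_speed`, `by_fixation`, `by_cell`, `rates_by_speed`
#'   (all per subject where a `subject` column is present).
#' @export
summarize_performance <- function(records, include_probes = FALSE) {
  if (!include_probes && "is_probe" %in% names(records))
    records <- records[!records$is_probe, ]
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  grp <- intersect("subject", names(records))
  pc <- function(...) {
    records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, ...)))) |>
      dplyr::summarise(n = dplyr::n(),
                       percent_correct = 100 * mean(.data$correct),
                       .groups = "drop")
  }
  rates <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "flight_duration_ms")))) |>
    dplyr::summarise(
      n_go = sum(.data$is_go), n_nogo = sum(!.data$is_go),
      hit_rate = sum(.data$response_type == "hit") / sum(.data$is_go),
      miss_rate = sum(.data$response_type == "miss") / sum(.data$is_go),
      cr_rate = sum(.data$response_type == "correct_rejection") / sum(!.data$is_go),
      fa_rate = sum(.data$response_type == "false_alarm") / sum(!.data$is_go),
      .groups = "drop"
    )
  structure(list(
    overall = pc(),
    by_block = pc("block"),
    by_speed = pc("flight_duration_ms"),
    by_fixation = pc("fixation_duration_ms"),
    by_cell = pc("flight_duration_ms", "fixation_duration_ms"),
    rates_by_speed = rates
  ), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  print(x$by_speed)
  invisible(x)
}

#' Reaction times of the simple reaction-time task
#'
#' Applies the task's filter rules: presses earlier than the 125 ms catch
#' threshold are catch trials, presses later than the 750 ms maximum (or
#' absent/negative presses) are invalid; remaining reaction times are
#' summarized as mean and SD.
#'
#' @param press_ms key-press time per trial relative to stimulus onset
#'   (`NA` for no press).
#' @param schedule an [generate_rtt_schedule()] schedule.
#' @return list of class `rtt_result`: `trials` tibble (`trial`, `rt_ms`,
#'   `status`) and `summary` (`n_included`, `mean_rt_ms`, `sd_rt_ms`,
#'   `n_catch`, `n_invalid`).
#' @export
rtt_reaction_times <- function(press_ms, schedule) {
  stopifnot(length(press_ms) == nrow(schedule))
  catch_thr <- attr(schedule, "catch_threshold_ms")
  max_rt <- attr(schedule, "max_rt_ms")
  status <- rep("ok", length(press_ms))
  status[is.na(press_ms)] <- "no_press"
  status[!is.na(press_ms) & press_ms < 0] <- "before_stimulus"
  status[!is.na(press_ms) & press_ms >= 0 & press_ms < catch_thr] <- "catch"
  status[!is.na(press_ms) & press_ms > max_rt] <- "invalid"
  ok <- status == "ok"
  structure(list(
    trials = tibble::tibble(trial = schedule$trial, rt_ms = press_ms,
                            status = status),
    summary = tibble::tibble(
      n_included = sum(ok),
      mean_rt_ms = if (any(ok)) mean(press_ms[ok]) else NA_real_,
      sd_rt_ms = if (sum(ok) > 1) sd(press_ms[ok]) else NA_real_,
      n_catch = sum(status == "catch"),
      n_invalid = sum(status %in% c("invalid", "no_press", "before_stimulus"))
    )
  ), class = "rtt_result")
}
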