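# File formats: schedules (JSON), session traces (CSV), ground truth
# (JSON), outcomes (CSV), QC log (JSON lines). All formats carry a schema
# version and are checked on read.

SCHEMA_VERSION <- "1.0"

SESSION_COLUMNS <- c("subject", "block", "trial_id", "t_ms", "gaze_x_deg",
                     "gaze_y_deg", "pupil_mm", "hand_speed_deg_s", "blink",
                     "touched", "touch_time_ms", "touch_x_deg", "touch_y_deg")

#' Write / read a trial schedule (JSON)
#'
#' The file holds a header (schema version, seed, geometry) and one object
#' per trial with all trial fields.
#'
#' @param schedule a schedule tibble.
#' @param geometry the [build_geometry()] object it was generated against.
#' @param path output path.
#' @return `write_schedule`: the path, invisibly. `read_schedule`: a list
#'   with `schedule` (tibble) and `geometry`.
#' @export
write_schedule <- function(schedule, geometry, path) {
  obj <- list(
    schema_version = SCHEMA_VERSION,
    seed = attr(schedule, "seed"),
    geometry = list(
      screen_width_deg = 2 * geometry$screen_halfwidth_deg,
      screen_height_deg = 2 * geometry$screen_halfheight_deg,
      fixation_pos = geometry$fixation_pos,
      target_center = geometry$target_center,
      target_side_deg = geometry$target_side_deg,
      grid_spacing_deg = geometry$grid_spacing_deg,
      viewing_distance_mm = geometry$viewing_distance_mm
    ),
    trials = as.data.frame(schedule)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stop("schedule file lacks a schema_version", call. = FALSE)
  g <- obj$geometry
  geometry <- build_geometry(
    screen_width_deg = g$screen_width_deg,
    screen_height_deg = g$screen_height_deg,
    fixation_pos = g$fixation_pos,
    target_center = g$target_center,
    target_side_deg = g$target_side_deg,
    grid_spacing_deg = g$grid_spacing_deg,
    viewing_distance_mm = g$viewing_distance_mm
  )
  sched <- tibble::as_tibble(obj$trials)
  sched$block <- as.integer(sched$block)
  attr(sched, "seed") <- obj$seed
  list(schedule = sched, geometry = geometry)
}

#' Write / read session traces (long CSV)
#'
#' One row per sample with columns subject, block, trial_id, t_ms,
#' gaze_x_deg, gaze_y_deg, pupil_mm, hand_speed_deg_s, blink, touched,
#' touch_time_ms, touch_x_deg, touch_y_deg.
#' On read, the presence of every column and the 200 Hz sample spacing
#' (5 ms within each trial) are checked; the ground truth, if written next
#' to the traces, lives in a sibling JSON file.
#'
#' @param session a `session_traces` object.
#' @param path CSV path; truth is written to `<path>_truth.json` when
#'   `with_truth` is TRUE.
#' @param with_truth also write the ground-truth table.
#' @return `write_session`: the path, invisibly. `read_session`: a list
#'   with `traces` and (if found) `truth`.
#' @export
write_session <- function(session, path, with_truth = TRUE) {
  write.csv(session$traces, path, row.names = FALSE)
  if (with_truth && !is.null(session$truth)) {
    jsonlite::write_json(
      list(schema_version = SCHEMA_VERSION,
           truth = as.data.frame(session$truth)),
      truth_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

truth_path <- function(path) sub("\\.csv$", "", path) |> paste0("_truth.json")

#' @rdname write_session
#' @param check_rate verify 5 ms spacing within trials (tolerance 0.5 ms).
#' @export
read_session <- function(path, check_rate = TRUE) {
  traces <- tibble::as_tibble(read.csv(path))
  missing <- setdiff(SESSION_COLUMNS, names(traces))
  if (length(missing))
    stop("session file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (check_rate) {
    dt <- unlist(tapply(traces$t_ms, traces$trial_id, diff,
                        simplify = FALSE), use.names = FALSE)
    if (length(dt) && any(abs(dt - SAMPLE_MS) > 0.5))
      stop("sample spacing is not 200 Hz (5 ms): found intervals of ",
           paste(round(range(dt), 2), collapse = "-"), " ms", call. = FALSE)
  }
  truth <- NULL
  tp <- truth_path(path)
  if (file.exists(tp))
    truth <- tibble::as_tibble(
      jsonlite::read_json(tp, simplifyVector = TRUE)$truth)
  list(traces = traces, truth = truth)
}

#' Write per-trial outcomes (CSV) and a QC log (JSON lines)
#'
#' @param outcomes an [extract_outcomes()] table.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  write.csv(as.data.frame(outcomes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) tibble::as_tibble(read.csv(path))

#' @rdname write_outcomes
#' @param qc_trials the `trials` table of a `clean_session`.
#' @export
write_qc_log <- function(qc_trials, path) {
  lines <- vapply(seq_len(nrow(qc_trials)), function(i) {
    jsonlite::toJSON(as.list(qc_trials[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
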