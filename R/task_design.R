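#' Build the task geometry
#'
#' Constructs the screen/stimulus geometry of the trajectory-prediction task:
#' a fixation cross high on the screen, a visible square target area near the
#' bottom, and eight possible final stimulus locations on a 4 x 2 grid. The
#' four inner grid columns fall strictly inside the target square (go
#' locations); the four outer ones fall outside it, two on each lateral side
#' (no-go locations). All coordinates are degrees of visual angle with the
#' origin at screen center and y pointing up.
#'
#' @param screen_width_deg,screen_height_deg full screen extent in degrees
#'   (defaults 75 x 46).
#' @param fixation_pos numeric length-2, fixation cross position (default
#'   `c(0, 20)`: 20 degrees above screen center).
#' @param target_center numeric length-2, center of the square target area.
#' @param target_side_deg side length of the target square (default 10).
#' @param grid_spacing_deg horizontal and vertical spacing between
#'   neighboring final locations (default 5, which places the inner columns
#'   at x = +/-2.5 and the outer ones at x = +/-7.5).
#' @param viewing_distance_mm eye-screen distance (default 460).
#'
#' @return An object of class `task_geometry`: a list with the arguments plus
#'   `final_locations`, a tibble with columns `index`, `x`, `y`, `is_go`.
#' @export
#' @examples
#' geom <- build_geometry()
#' geom$final_locations
build_geometry <- function(screen_width_deg = 75,
                           screen_height_deg = 46,
                           fixation_pos = c(0, 20),
                           target_center = c(0, -15),
                           target_side_deg = 10,
                           grid_spacing_deg = 5,
                           viewing_distance_mm = 460) {
  if (screen_width_deg <= 0 || screen_height_deg <= 0)
    stop("screen extent must be positive", call. = FALSE)
  if (target_side_deg <= 0)
    stop("target square side must be positive", call. = FALSE)
  if (target_side_deg > screen_height_deg)
    stop("target square side exceeds screen height", call. = FALSE)
  if (grid_spacing_deg <= 0)
    stop("grid spacing must be positive", call. = FALSE)

  cx <- target_center[1]; cy <- target_center[2]
  xs <- cx + grid_spacing_deg * c(-1.5, -0.5, 0.5, 1.5)
  ys <- cy + grid_spacing_deg * c(0.5, -0.5)
  grid <- expand.grid(x = xs, y = ys)
  half <- target_side_deg / 2
  inside <- abs(grid$x - cx) < half & abs(grid$y - cy) < half
  locs <- tibble::tibble(
    index = seq_len(nrow(grid)),
    x = grid$x, y = grid$y, is_go = inside
  )

  if (sum(locs$is_go) != 4L)
    stop("geometry invalid: expected exactly 4 go locations inside the target square, got ",
         sum(locs$is_go), call. = FALSE)
  left_out  <- sum(!locs$is_go & locs$x < cx - half)
  right_out <- sum(!locs$is_go & locs$x > cx + half)
  if (left_out != 2L || right_out != 2L)
    stop("geometry invalid: no-go locations must lie outside the target square, two on each lateral side",
         call. = FALSE)
  if (fixation_pos[2] <= cy)
    stop("geometry invalid: fixation cross must lie above the target center", call. = FALSE)
  if (any(abs(locs$x) > screen_width_deg / 2) || any(abs(locs$y) > screen_height_deg / 2))
    stop("geometry invalid: final locations fall off screen", call. = FALSE)

  structure(
    list(
      screen_halfwidth_deg = screen_width_deg / 2,
      screen_halfheight_deg = screen_height_deg / 2,
      fixation_pos = as.numeric(fixation_pos),
      target_center = as.numeric(target_center),
      target_side_deg = target_side_deg,
      grid_spacing_deg = grid_spacing_deg,
      viewing_distance_mm = viewing_distance_mm,
      final_locations = locs
    ),
    class = "task_geometry"
  )
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("<task_geometry> screen", 2 * x$screen_halfwidth_deg, "x",
      2 * x$screen_halfheight_deg, "deg; fixation at (",
      x$fixation_pos[1], ",", x$fixation_pos[2], "); target",
      x$target_side_deg, "deg square at (", x$target_center[1], ",",
      x$target_center[2], ");", sum(x$final_locations$is_go), "go /",
      sum(!x$final_locations$is_go), "no-go locations\n")
  invisible(x)
}

# Canonical trial timing levels (ms).
TPT_SPEEDS <- c(385, 485, 585)
TPT_FIXATIONS <- c(390, 890, 1900)
TPT_PROBE_FLIGHT <- 985
TPT_PROBE_FIXATION <- 1000
TPT_FEEDBACK_MS <- 500
TPT_JITTER_CHOICES <- c(-5, 0, 5)

#' Generate one counterbalanced trajectory-task block
#'
#' Produces an 80-trial block under the default design: 3 flight speeds
#' (385/485/585 ms) x 8 final locations x 3 repetitions, plus 8 slow probe
#' trials (985 ms flight, one per location, fixation 1000 ms). Fixation
#' durations (390/890/1900 ms) are counterbalanced so that each duration
#' occurs 24 times per block, once per speed within every location. Each
#' trial draws a duration jitter from {-5, 0, +5} ms emulating the
#' 60 Hz screen / 200 Hz recording asynchrony. Trial order is a seeded
#' permutation; identical `(design, seed)` yield identical schedules.
#'
#' The counterbalance is constructed exactly (per location and speed, a
#' seeded permutation of the fixation durations across repetitions), so the
#' count invariants hold by construction whenever `n_reps` is a multiple of
#' the number of fixation durations.
#'
#' @param geometry a [build_geometry()] object.
#' @param seed integer seed; the schedule is a deterministic function of it.
#' @param block block index stored on each trial (default 1).
#' @param n_reps repetitions per speed x location cell (default 3).
#' @param speeds,fixations flight-speed and fixation-duration levels in ms.
#' @param probes_per_location number of probe trials per final location.
#' @param probe_flight_ms,probe_fixation_ms probe timing (defaults 985/1000).
#' @param jitter_choices candidate per-trial duration jitters in ms.
#'
#' @return A tibble (class `block_schedule`) with one row per trial:
#'   `trial_id`, `block`, `fixation_duration_ms`, `flight_duration_ms`,
#'   `jitter_ms`, `final_location_index`, `is_go`, `is_probe`,
#'   `feedback_duration_ms`.
#' @export
generate_tpt_block <- function(geometry, seed, block = 1L,
                               n_reps = 3L,
                               speeds = TPT_SPEEDS,
                               fixations = TPT_FIXATIONS,
                               probes_per_location = 1L,
                               probe_flight_ms = TPT_PROBE_FLIGHT,
                               probe_fixation_ms = TPT_PROBE_FIXATION,
                               jitter_choices = TPT_JITTER_CHOICES) {
  stopifnot(inherits(geometry, "task_geometry"))
  locs <- geometry$final_locations
  n_loc <- nrow(locs)

  empty <- tibble::tibble(
    trial_id = character(), block = integer(),
    fixation_duration_ms = numeric(), flight_duration_ms = numeric(),
    jitter_ms = numeric(), final_location_index = integer(),
    is_go = logical(), is_probe = logical(), feedback_duration_ms = numeric()
  )
  if (n_reps == 0L && probes_per_location == 0L) {
    return(structure(empty, class = c("block_schedule", class(empty)),
                     seed = seed, block_index = block))
  }
  if (n_reps > 0L && n_reps %% length(fixations) != 0L) {
    stop("infeasible design: repetitions per speed x location (", n_reps,
         ") must be a multiple of the number of fixation durations (",
         length(fixations), ") for an exact counterbalance", call. = FALSE)
  }

  withr::with_seed(seed, {
    rows <- list()
    if (n_reps > 0L) {
      chunks <- n_reps %/% length(fixations)
      for (loc in seq_len(n_loc)) {
        for (sp in speeds) {
          fix_seq <- unlist(lapply(seq_len(chunks),
                                   function(i) sample(fixations)))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            fixation_duration_ms = fix_seq,
            flight_duration_ms = sp,
            final_location_index = loc,
            is_probe = FALSE
          )
        }
      }
    }
    if (probes_per_location > 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fixation_duration_ms = probe_fixation_ms,
        flight_duration_ms = probe_flight_ms,
        final_location_index = rep(seq_len(n_loc), each = probes_per_location),
        is_probe = TRUE
      )
    }
    sched <- dplyr::bind_rows(rows)
    sched <- sched[sample.int(nrow(sched)), ]
    sched$jitter_ms <- sample(jitter_choices, nrow(sched), replace = TRUE)
    sched$is_go <- locs$is_go[sched$final_location_index]
    sched$block <- as.integer(block)
    sched$feedback_duration_ms <- TPT_FEEDBACK_MS
    sched$trial_id <- sprintf("b%d_t%03d", block, seq_len(nrow(sched)))
    sched <- sched[, names(empty)]
    structure(sched, class = c("block_schedule", class(sched)),
              seed = seed, block_index = block)
  })
}

#' Generate a multi-block trajectory-task schedule
#'
#' @param geometry a [build_geometry()] object.
#' @param blocks number of blocks (default 3).
#' @param seed integer seed; per-block seeds are derived deterministically.
#' @param ... passed to [generate_tpt_block()].
#' @return A tibble of `blocks * 80` trials (under the default design).
#' @export
generate_tpt_schedule <- function(geometry, blocks = 3L, seed = 1L, ...) {
  block_seeds <- withr::with_seed(seed, sample.int(2^31 - 1, blocks))
  out <- dplyr::bind_rows(lapply(seq_len(blocks), function(b) {
    generate_tpt_block(geometry, seed = block_seeds[b], block = b, ...)
  }))
  structure(out, class = c("block_schedule", class(tibble::tibble())),
            seed = seed)
}

#' Check the count invariants of a trajectory-task block
#'
#' Asserts, for each block in the schedule: 80 trials; 24 trials per
#' non-probe speed with exactly 3 per final location; 8 probes, one per
#' location; 24 trials per fixation duration (probes counted under their own
#' 1000 ms duration); every location targeted 10 times; go labels consistent
#' with the geometry.
#'
#' @param schedule a schedule from [generate_tpt_block()] /
#'   [generate_tpt_schedule()].
#' @param geometry the geometry the schedule was generated against.
#' @return `TRUE` invisibly, or an error describing the violated constraint.
#' @export
validate_block_schedule <- function(schedule, geometry) {
  fail <- function(...) stop("schedule invariant violated: ", ..., call. = FALSE)
  for (b in unique(schedule$block)) {
    s <- schedule[schedule$block == b, ]
    if (nrow(s) != 80L) fail("block ", b, " has ", nrow(s), " trials, expected 80")
    np <- s[!s$is_probe, ]
    spd <- table(np$flight_duration_ms)
    if (!all(spd == 24L)) fail("trials per speed != 24 in block ", b)
    cell <- table(np$flight_duration_ms, np$final_location_index)
    if (!all(cell == 3L)) fail("speed x location cells != 3 in block ", b)
    pr <- s[s$is_probe, ]
    if (nrow(pr) != 8L) fail("block ", b, " has ", nrow(pr), " probes, expected 8")
    if (!all(table(pr$final_location_index) == 1L))
      fail("probes not one per location in block ", b)
    if (!all(pr$flight_duration_ms == TPT_PROBE_FLIGHT))
      fail("probe flight duration != 985 ms")
    if (!all(pr$fixation_duration_ms == TPT_PROBE_FIXATION))
      fail("probe fixation duration != 1000 ms")
    fx <- table(np$fixation_duration_ms)
    if (!all(fx == 24L)) fail("trials per fixation duration != 24 in block ", b)
    locn <- table(s$final_location_index)
    if (!all(locn == 10L)) fail("locations not targeted 10 times each in block ", b)
    if (!all(abs(s$jitter_ms) <= 5)) fail("jitter outside +/-5 ms")
    if (!all(s$is_go == geometry$final_locations$is_go[s$final_location_index]))
      fail("go labels inconsistent with geometry in block ", b)
  }
  invisible(TRUE)
}

#' Generate a simple reaction-time task schedule
#'
#' 50 trials with a 500 ms stimulus, intertrial intervals drawn uniformly
#' from 1.5-4 s, a break after trial 25, a 125 ms catch threshold, and a
#' 750 ms maximum allowed reaction time.
#'
#' @param seed integer seed.
#' @param n_trials number of trials (default 50).
#' @return A tibble (class `rtt_schedule`) with columns `trial`, `iti_ms`,
#'   `stimulus_duration_ms`; attributes `catch_threshold_ms` (125),
#'   `max_rt_ms` (750), `break_after` (25).
#' @export
generate_rtt_schedule <- function(seed, n_trials = 50L) {
  sched <- withr::with_seed(seed, tibble::tibble(
    trial = seq_len(n_trials),
    iti_ms = runif(n_trials, 1500, 4000),
    stimulus_duration_ms = 500
  ))
  structure(sched, class = c("rtt_schedule", class(sched)),
            seed = seed, catch_threshold_ms = 125, max_rt_ms = 750,
            break_after = 25L)
}

#' Stimulus position along its straight-line trajectory
#'
#' The stimulus leaves the fixation cross at stimulus onset and travels at
#' constant speed in a straight line to the trial's final location, arriving
#' at the effective flight duration (nominal flight duration + jitter).
#'
#' @param spec one schedule row (a one-row data frame or a list with
#'   `flight_duration_ms`, `jitter_ms`, `final_location_index`).
#' @param geometry a [build_geometry()] object.
#' @param t_ms time(s) since stimulus onset, in ms; all values must lie in
#'   `[0, flight_duration_ms + jitter_ms]`.
#' @return A two-column matrix of x/y positions in degrees.
#' @export
stimulus_position <- function(spec, geometry, t_ms) {
  dur <- spec$flight_duration_ms + spec$jitter_ms
  if (any(t_ms < 0 | t_ms > dur))
    stop("t_ms outside the flight window [0, ", dur, "]", call. = FALSE)
  loc <- geometry$final_locations[spec$final_location_index, ]
  frac <- t_ms / dur
  cbind(
    x = geometry$fixation_pos[1] + frac * (loc$x - geometry$fixation_pos[1]),
    y = geometry$fixation_pos[2] + frac * (loc$y - geometry$fixation_pos[2])
  )
}
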