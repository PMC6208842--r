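# End-to-end pipeline: design -> simulate -> extract -> summarize ->
# compare, fully seeded, with a manifest tying every output to the
# configuration hash.

#' Pipeline configuration
#'
#' A single nested list holding every tunable of the pipeline. Defaults
#' equal the task's printed constants (design counts and timing levels,
#' detector thresholds 50 deg/s / 8 deg / 20 deg/s, 100 ms pupil windows,
#' 125/750 ms reaction-time rules) and the package's documented QC rules.
#' Configurations can be stored as YAML or JSON and reloaded.
#'
#' @param n_per_group simulated subjects per group (expert/control).
#' @param blocks blocks per subject.
#' @param seed master seed; all stage seeds derive from it.
#' @param geometry,qc,detectors component configurations.
#' @param sdt_correction extreme-rate correction rule for d-prime.
#' @param include_probes include probe trials in performance summaries.
#' @param design list of design counts/levels passed to
#'   [generate_tpt_block()].
#' @param profiles optional named list of field overrides per group, e.g.
#'   `list(expert = list(pupil_noise_sd_mm = 0.01))`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 2L, blocks = 3L, seed = 1L,
                            geometry = list(),
                            qc = qc_config(),
                            detectors = detector_config(),
                            sdt_correction = "loglinear",
                            include_probes = FALSE,
                            design = list(),
                            profiles = list()) {
  structure(list(n_per_group = n_per_group, blocks = blocks, seed = seed,
                 geometry = geometry, qc = qc, detectors = detectors,
                 sdt_correction = sdt_correction,
                 include_probes = include_probes, design = design,
                 profiles = profiles, schema_version = SCHEMA_VERSION),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        names(formals(pipeline_config)))]
  if (!is.null(args$qc)) args$qc <- do.call(qc_config, args$qc)
  if (!is.null(args$detectors))
    args$detectors <- do.call(detector_config, args$detectors)
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Generates schedules, simulates an expert and a control cohort, cleans
#' and extracts outcomes, classifies responses, summarizes performance and
#' signal detection per group, runs the group comparison on percent
#' correct, and writes every artifact plus a manifest into `out_dir`.
#' Deterministic: the same configuration produces identical summary files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results: `outcomes`,
#'   `records`, `summary_by_group`, `dprime_by_group`, `comparison`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  geometry <- stage("design", do.call(build_geometry, config$geometry))
  seeds <- withr::with_seed(config$seed,
                            sample.int(2^31 - 1, 2 * config$n_per_group + 1))
  schedule <- stage("design", do.call(generate_tpt_schedule, c(
    list(geometry = geometry, blocks = config$blocks, seed = seeds[1]),
    config$design)))
  stage("design", validate_block_schedule(schedule, geometry))
  write_schedule(schedule, geometry, file.path(out_dir, "schedule.json"))

  subjects <- tibble::tibble(
    subject = sprintf("%s%02d", rep(c("expert", "control"),
                                    each = config$n_per_group),
                      rep(seq_len(config$n_per_group), 2)),
    group = rep(c("expert", "control"), each = config$n_per_group)
  )

  outcomes <- list(); qc_counts <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]; grp <- subjects$group[i]
    overrides <- config$profiles[[grp]] %||% list()
    profile <- do.call(subject_profile, c(list(group = grp), overrides))
    sess <- stage("simulate",
                  simulate_session(profile, schedule, geometry,
                                   seed = seeds[i + 1], subject = sid))
    write_session(sess, file.path(out_dir, paste0(sid, "_session.csv")))
    clean <- stage("extract", clean_traces(sess, geometry, config$qc))
    write_qc_log(clean$trials, file.path(out_dir, paste0(sid, "_qc.jsonl")))
    out <- stage("extract", extract_outcomes(clean, geometry, config$detectors))
    out$group <- grp
    outcomes[[sid]] <- out
    qc_counts[[sid]] <- table(factor(clean$trials$valid, c(FALSE, TRUE)))
  }
  outcomes <- dplyr::bind_rows(outcomes)
  write_outcomes(outcomes, file.path(out_dir, "outcomes.csv"))

  records <- stage("summarize", classify_trials(outcomes))
  summary_by_group <- lapply(split(records, records$group),
                             summarize_performance,
                             include_probes = config$include_probes)
  dp <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dprime_by_condition(
      .x, correction = config$sdt_correction,
      include_probes = config$include_probes)) |>
    dplyr::ungroup()
  perf <- dplyr::bind_rows(lapply(names(summary_by_group), function(g)
    dplyr::mutate(summary_by_group[[g]]$by_speed, group = g)))
  write.csv(as.data.frame(perf), file.path(out_dir, "summary_by_speed.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(dp), file.path(out_dir, "dprime_by_group.csv"),
            row.names = FALSE)

  comparison <- stage("compare", {
    pc <- records |>
      dplyr::group_by(.data$subject, .data$group) |>
      dplyr::summarise(percent_correct = 100 * mean(.data$correct),
                       .groups = "drop")
    if (config$n_per_group >= 2)
      group_compare(pc, "percent_correct") else NULL
  })
  if (!is.null(comparison))
    jsonlite::write_json(as.data.frame(comparison),
                         file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package = "trajtask",
    version = as.character(packageVersion("trajtask")),
    schema_version = SCHEMA_VERSION,
    seed = config$seed,
    stage_seeds = seeds,
    config_hash = rlang::hash(unclass(config)),
    n_subjects = nrow(subjects),
    n_trials_per_subject = nrow(schedule),
    qc_valid_trials = sapply(qc_counts, function(x) unname(x["TRUE"])),
    qc_rejected_trials = sapply(qc_counts, function(x) unname(x["FALSE"]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(outcomes = outcomes, records = records,
                 summary_by_group = summary_by_group,
                 dprime_by_group = dp, comparison = comparison,
                 manifest = manifest))
}
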