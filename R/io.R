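#' CSV readers and writers for the pipeline's tables
#'
#' Plain-CSV dialects used by every stage. Gaze: `trial_id, t, x_deg, y_deg`
#' (plus `participant` for cohorts). Events: `trial_id, time, kind`.
#' Designs: one row per trial with the design factors and derived event
#' times. Readers validate the required columns and fail with a message
#' naming any missing one.
#'
#' @param gaze,events,design,scores Tibbles to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name gazepred_io
NULL

#' @rdname gazepred_io
#' @export
write_gaze_csv <- function(gaze, path) {
  check_columns(gaze, c("trial_id", "t", "x"), "gaze")
  out <- gaze %>% rename(x_deg = "x", y_deg = "y")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname gazepred_io
#' @export
read_gaze_csv <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(g, c("trial_id", "t", "x_deg", "y_deg"), "gaze CSV")
  g %>% rename(x = "x_deg", y = "y_deg")
}

#' @rdname gazepred_io
#' @export
write_events_csv <- function(events, path) {
  check_columns(events, c("trial_id", "time", "kind"), "events")
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname gazepred_io
#' @export
read_events_csv <- function(path) {
  e <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(e, c("trial_id", "time", "kind"), "events CSV")
  e
}

#' @rdname gazepred_io
#' @export
write_design_csv <- function(design, path) {
  design <- fill_design_defaults(design)
  out <- design %>%
    mutate(
      motion_onset = .data$pre_motion,
      change_onset = .data$pre_motion + .data$pre_change_duration,
      occlusion_time = .data$change_onset + .data$occlusion,
      ttc = .data$change_onset +
        (.data$initial_eccentricity -
           .data$pre_change_speed * .data$pre_change_duration) / .data$speed
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname gazepred_io
#' @export
read_design_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(d, c("trial_id", "speed", "occlusion", "side"), "design CSV")
  fill_design_defaults(d)
}

#' @rdname gazepred_io
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A serializable bundle of every tunable in the pipeline, with defaults
#' equal to the reference analysis values: 22 deg/s saccade threshold,
#' 60 Hz velocity low-pass, 16/70 ms peri-saccadic exclusion margins, 3 deg
#' gaze-distance criterion, minimum 10 valid trials per cell.
#'
#' @param experiment 1, 2 or 3.
#' @param n_participants Cohort size for simulation.
#' @param seed Integer seed.
#' @param oculomotor Named list of [oculomotor_params()] overrides.
#' @param velocity_threshold,cutoff,pre_margin,post_margin,dist_threshold,min_valid
#'   Pipeline thresholds (deg/s, Hz, s, s, deg, trials).
#' @param measure Dependent variable analysed by [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = 1, n_participants = 12, seed = 1,
                       oculomotor = list(),
                       velocity_threshold = 22, cutoff = 60,
                       pre_margin = 0.016, post_margin = 0.070,
                       dist_threshold = 3, min_valid = 10,
                       measure = c("percent_correct", "rt", "ttc_error",
                                   "relative_ttc")) {
  measure <- match.arg(measure)
  cfg <- list(
    experiment = experiment, n_participants = n_participants, seed = seed,
    oculomotor = oculomotor, velocity_threshold = velocity_threshold,
    cutoff = cutoff, pre_margin = pre_margin, post_margin = post_margin,
    dist_threshold = dist_threshold, min_valid = min_valid, measure = measure
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' End-to-end pipeline: design, simulate, detect, score, analyse
#'
#' Runs the full chain for one configuration: generates the experiment
#' design, simulates the cohort, detects saccades and scores every trial,
#' aggregates to the participant x condition table, and fits the
#' within-subject ANOVA on the configured measure.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, the design, trial scores,
#'   aggregate table and ANOVA table are written there as CSV.
#' @return A list: `design`, `scores`, `aggregate`, `anova` (an
#'   [rm_anova()] object or `NULL` if too few participants survive
#'   exclusion), `excluded`.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  params <- do.call(oculomotor_params, cfg$oculomotor)
  run <- run_experiment(
    experiment = cfg$experiment, n_participants = cfg$n_participants,
    params = params, seed = cfg$seed,
    dist_threshold = cfg$dist_threshold,
    velocity_threshold = cfg$velocity_threshold, cutoff = cfg$cutoff
  )
  agg <- aggregate_scores(run$scores, min_valid = cfg$min_valid)
  dv <- switch(cfg$measure,
               percent_correct = "percent_correct",
               rt = "mean_rt", ttc_error = "mean_ttc_error",
               relative_ttc = "mean_relative_ttc")
  anova <- NULL
  if (length(unique(agg$participant)) >= 2) {
    anova <- rm_anova(agg, dv = dv, id = "participant",
                      within = c("speed", "occlusion"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design_csv(run$design, file.path(out_dir, "design.csv"))
    write_scores_csv(run$scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(agg, file.path(out_dir, "aggregate.csv"))
    if (!is.null(anova)) {
      readr::write_csv(tidy(anova), file.path(out_dir, "anova.csv"))
    }
  }
  list(design = run$design, scores = run$scores, aggregate = agg,
       anova = anova, excluded = excluded_participants(agg))
}
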