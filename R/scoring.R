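#' Score one trial: validity, correctness, response times, TTC error
#'
#' Applies the trial-level analysis rules of the paradigm:
#'
#' * **Validity** -- the trial is invalid if the gaze-target distance exceeds
#'   the 3 deg criterion during the pursuit phase (motion onset until the
#'   response saccade or the occlusion, whichever comes first, i.e. while
#'   tracking the visible target) or, in saccade mode after the response
#'   saccade has landed, if the gaze-cross distance exceeds 3 deg before the
#'   TTC response. The comparison is strict (`> 3` invalidates; 3.0 exactly
#'   is still valid).
#' * **Correctness** -- a perturbation trial is correct when a qualifying
#'   saccade (initiated after change onset, endpoint within 3 deg of the
#'   cross) occurs; a catch trial is correct when none occurs. In pursuit
#'   mode a `perturbation_response` button press substitutes for the
#'   saccade. A qualifying saccade initiated before change onset
#'   (anticipation) makes the trial incorrect.
#' * **Saccadic / perturbation response time** -- first qualifying saccade
#'   onset (or perturbation button press) minus change onset; only defined
#'   for correct perturbation trials.
#' * **TTC prediction error** -- signed `press - ttc` (s) from the
#'   `ttc_response` button, and the relative TTC
#'   `100 * (press - change_onset) / (ttc - change_onset)` (%), 0% at change
#'   onset and 100% at the true TTC; only scored on correct trials.
#'
#' @param gaze Tibble `t`, `x`, `y` for the trial.
#' @param timeline The trial's [build_timeline()] object.
#' @param buttons Tibble `time`, `kind` of button events (may be empty).
#' @param mode `"saccade"` (Experiments 1-2) or `"pursuit"` (Experiment 3).
#' @param saccades Optional pre-computed [detect_saccades()] table; computed
#'   from `gaze` when `NULL`.
#' @param dist_threshold Gaze-distance validity/landing criterion, deg.
#' @param velocity_threshold,cutoff Saccade-detection settings used when
#'   `saccades` is `NULL`.
#' @param settle Time allowed for post-saccadic settling before the fixation
#'   -phase distance check starts, s.
#' @return A one-row tibble: `trial_id`, `valid`, `correct`, `saccadic_rt`,
#'   `perturbation_rt`, `ttc_error`, `relative_ttc`, `n_saccades`.
#' @export
score_trial <- function(gaze, timeline, buttons = NULL,
                        mode = c("saccade", "pursuit"), saccades = NULL,
                        dist_threshold = 3, velocity_threshold = 22,
                        cutoff = 60, settle = 0.070) {
  mode <- match.arg(mode)
  if (is.null(buttons)) buttons <- tibble(time = numeric(), kind = character())
  check_columns(buttons, c("time", "kind"), "buttons")
  if (is.null(saccades)) {
    saccades <- detect_saccades(compute_velocity(gaze, cutoff = cutoff),
                                threshold = velocity_threshold)
  }
  dist <- distance_series(gaze, timeline)
  change <- timeline$change_onset
  perturbation <- timeline$design$speed != timeline$design$pre_change_speed

  # qualifying saccades: endpoint within dist_threshold of the cross
  land_dist <- vapply(seq_len(nrow(saccades)), function(i) {
    j <- which.min(abs(gaze$t - saccades$offset[i]))
    sqrt(gaze$x[j]^2 + (if ("y" %in% names(gaze)) gaze$y[j] else 0)^2)
  }, numeric(1))
  qualifying <- saccades[land_dist <= dist_threshold, ]
  anticipatory <- nrow(qualifying) > 0 && any(qualifying$onset <= change)
  post_change <- qualifying[qualifying$onset > change, ]

  if (mode == "saccade") {
    responded <- nrow(post_change) > 0
    response_onset <- if (responded) min(post_change$onset) else NA_real_
    response_offset <- if (responded) {
      post_change$offset[which.min(post_change$onset)]
    } else NA_real_
  } else {
    presses <- buttons$time[buttons$kind == "perturbation_response" &
                              buttons$time > change]
    responded <- length(presses) > 0
    response_onset <- if (responded) min(presses) else NA_real_
    response_offset <- NA_real_
  }

  # --- validity ------------------------------------------------------------
  pursuit_end <- if (mode == "saccade" && responded) {
    min(response_onset, timeline$occlusion_time)
  } else timeline$occlusion_time
  in_pursuit <- dist$t >= timeline$motion_onset & dist$t < pursuit_end
  valid <- !any(dist$dist_circle[in_pursuit] > dist_threshold)
  ttc_presses <- buttons$time[buttons$kind == "ttc_response"]
  if (mode == "saccade" && responded && !is.na(response_offset)) {
    fix_end <- if (length(ttc_presses) > 0) min(ttc_presses) else max(dist$t)
    in_fix <- dist$t >= response_offset + settle & dist$t <= fix_end
    valid <- valid && !any(dist$dist_cross[in_fix] > dist_threshold)
  }

  # --- correctness ---------------------------------------------------------
  correct <- if (anticipatory) FALSE
  else if (perturbation) responded
  else !responded

  rt <- if (correct && perturbation && responded) response_onset - change
  else NA_real_

  # --- TTC prediction ------------------------------------------------------
  ttc_error <- relative_ttc <- NA_real_
  if (correct && length(ttc_presses) > 0) {
    press <- min(ttc_presses)
    ttc_error <- press - timeline$ttc
    relative_ttc <- 100 * (press - change) / (timeline$ttc - change)
  }

  tibble(
    trial_id = timeline$design$trial_id,
    mode = mode, valid = valid, correct = correct,
    saccadic_rt = if (mode == "saccade") rt else NA_real_,
    perturbation_rt = if (mode == "pursuit") rt else NA_real_,
    ttc_error = ttc_error, relative_ttc = relative_ttc,
    n_saccades = nrow(saccades)
  )
}

#' Score every trial of a simulated cohort
#'
#' Runs the detection and scoring chain ([compute_velocity()],
#' [detect_saccades()], [score_trial()]) on each participant x trial of a
#' [simulate_cohort()] result.
#'
#' @param cohort List with `gaze`, `events` tibbles as returned by
#'   [simulate_cohort()].
#' @param design The design tibble the cohort was simulated from.
#' @param mode Passed to [score_trial()].
#' @param ... Further arguments to [score_trial()].
#' @return A tibble with one row per participant x trial: the
#'   [score_trial()] columns plus `participant`, `speed`, `occlusion`.
#' @export
score_trials <- function(cohort, design, mode = c("saccade", "pursuit"), ...) {
  mode <- match.arg(mode)
  design <- fill_design_defaults(design)
  keys <- distinct(cohort$gaze[, c("participant", "trial_id")])
  scores <- purrr::pmap(keys, function(participant, trial_id) {
    g <- cohort$gaze[cohort$gaze$participant == participant &
                       cohort$gaze$trial_id == trial_id, ]
    b <- cohort$events[cohort$events$participant == participant &
                         cohort$events$trial_id == trial_id, ]
    tl <- build_timeline(design[design$trial_id == trial_id, ])
    score_trial(g, tl, buttons = b, mode = mode, ...) %>%
      mutate(participant = participant, .before = 1)
  })
  bind_rows(scores) %>%
    left_join(select(design, "trial_id", "speed", "occlusion"),
              by = "trial_id")
}

#' Simulate and score a whole experiment without storing raw gaze
#'
#' Memory-light end-to-end run: for each participant and trial the gaze is
#' simulated, saccades detected, and the trial scored; only the per-trial
#' scores and ground truth are kept.
#'
#' @param experiment 1, 2 or 3 (3 selects pursuit mode automatically).
#' @param n_participants Cohort size.
#' @param params A single [oculomotor_params()] or a named per-participant
#'   list.
#' @param seed Integer seed.
#' @param design Optional design tibble; defaults to
#'   `generate_design(experiment, seed)`.
#' @param mode Response mode; default `"pursuit"` for experiment 3,
#'   `"saccade"` otherwise.
#' @param ... Further arguments to [score_trial()].
#' @return A list: `scores` (participant x trial tibble with scores, design
#'   factors and ground-truth columns) and `design`.
#' @export
run_experiment <- function(experiment = 1, n_participants = 12,
                           params = oculomotor_params(), seed = 1,
                           design = NULL, mode = NULL, ...) {
  if (is.null(mode)) mode <- if (experiment == 3) "pursuit" else "saccade"
  if (inherits(params, "oculomotor_params")) {
    params <- setNames(rep(list(params), n_participants),
                       paste0("P", seq_len(n_participants)))
  }
  if (is.null(names(params)) || anyDuplicated(names(params))) {
    stop("participant ids (names of `params`) must be unique", call. = FALSE)
  }
  with_rng_seed(seed, {
    if (is.null(design)) {
      design <- generate_design(experiment,
                                seed = sample.int(.Machine$integer.max, 1))
    }
    design <- fill_design_defaults(design)
    timelines <- purrr::map(seq_len(nrow(design)),
                            ~build_timeline(design[.x, ]))
    rows <- purrr::imap(params, function(pp, pid) {
      purrr::map(seq_len(nrow(design)), function(i) {
        sim <- simulate_trial_impl(timelines[[i]], pp, mode,
                                   1 / pp$sample_rate)
        sc <- score_trial(sim$gaze, timelines[[i]], buttons = sim$events,
                          mode = mode, ...)
        sc$participant <- pid
        bind_cols(sc, sim$truth %>%
                    select("perturbation", "detected", "false_alarm",
                           "detection_time", "sacc_onset", "true_ttc",
                           "intended_valid"))
      }) %>% bind_rows()
    })
    scores <- bind_rows(rows) %>%
      left_join(select(design, "trial_id", "speed", "occlusion"),
                by = "trial_id")
    list(scores = scores, design = design)
  })
}

#' Aggregate trial scores into a participant x condition table
#'
#' Summarises scored trials per participant x speed x occlusion cell and
#' applies the participant-exclusion rule: a participant with fewer than
#' `min_valid` valid trials in any cell is flagged and dropped from the
#' returned table (the table feeding the within-subject statistics).
#'
#' @param scores Tibble from [score_trials()] / [run_experiment()].
#' @param min_valid Minimum number of valid trials per cell.
#' @return A tibble with one row per retained participant x cell:
#'   `n_trials`, `n_valid`, `n_correct`, `percent_correct`, mean/median
#'   response time and TTC error, mean relative TTC. The ids of excluded
#'   participants are in `attr(, "excluded")` (also via
#'   [excluded_participants()]).
#' @export
aggregate_scores <- function(scores, min_valid = 10) {
  if (nrow(scores) == 0) stop("`scores` is empty", call. = FALSE)
  check_columns(scores, c("participant", "speed", "occlusion", "valid",
                          "correct"), "scores")
  rt <- dplyr::coalesce(
    if ("saccadic_rt" %in% names(scores)) scores$saccadic_rt else NA_real_,
    if ("perturbation_rt" %in% names(scores)) scores$perturbation_rt else NA_real_
  )
  scores$.rt <- rt
  cells <- scores %>%
    group_by(.data$participant, .data$speed, .data$occlusion) %>%
    summarise(
      n_trials = dplyr::n(),
      n_valid = sum(.data$valid),
      n_correct = sum(.data$valid & .data$correct),
      percent_correct = 100 * .data$n_correct / max(.data$n_valid, 1L),
      mean_rt = mean(.data$.rt[.data$valid], na.rm = TRUE),
      median_rt = median(.data$.rt[.data$valid], na.rm = TRUE),
      mean_ttc_error = mean(.data$ttc_error[.data$valid], na.rm = TRUE),
      median_ttc_error = median(.data$ttc_error[.data$valid], na.rm = TRUE),
      mean_relative_ttc = mean(.data$relative_ttc[.data$valid], na.rm = TRUE),
      .groups = "drop"
    )
  excluded <- cells %>%
    group_by(.data$participant) %>%
    summarise(min_cell = min(.data$n_valid), .groups = "drop") %>%
    filter(.data$min_cell < min_valid) %>%
    pull(.data$participant)
  out <- cells %>% filter(!.data$participant %in% excluded)
  attr(out, "excluded") <- excluded
  out
}

#' @rdname aggregate_scores
#' @param table A table returned by [aggregate_scores()].
#' @export
excluded_participants <- function(table) {
  attr(table, "excluded") %||% character()
}
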