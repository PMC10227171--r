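#' Oculomotor parameters of the synthetic gaze generator
#'
#' Bundles every behavioural and apparatus parameter of the simulator. The
#' defaults emulate the reference apparatus and cohort: a 200 Hz gaze-vector
#' stream (5 ms update), smooth pursuit with gain just below 1 and ~150 ms
#' onset latency, perturbation-detection latency of 300 +/- 50 ms, saccades
#' on the main sequence (peak velocity = 30 deg/s per degree of amplitude,
#' raised-cosine velocity profile), slow fixational drift bounded by the
#' tracker's ~0.5 deg accuracy, and roughly 30% of trials invalidated by
#' gaze drifting beyond the 3 deg criterion.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param pursuit_gain Ratio of eye to target velocity during pursuit.
#' @param pursuit_latency Pursuit onset latency after motion onset, s.
#' @param detection_latency_mean,detection_latency_sd Gaussian latency of
#'   perturbation detection (saccade or button initiation), s.
#' @param miss_rate Probability that a perturbation goes undetected.
#' @param false_alarm_rate Probability of a spurious response on a catch
#'   (no-perturbation) trial.
#' @param main_sequence_slope Peak saccade velocity per degree of amplitude,
#'   (deg/s)/deg; with the raised-cosine profile the saccade duration is
#'   `2 / main_sequence_slope` seconds.
#' @param landing_noise_sd SD of saccade landing error around the cross, deg.
#' @param fixation_noise_sd,pursuit_noise_sd SD of slow (AR(1)) oculomotor
#'   drift noise during fixation / pursuit, deg.
#' @param noise_tau Correlation time of the slow drift noise, s.
#' @param measurement_noise_sd SD of white per-sample tracker noise, deg.
#' @param vertical_noise_sd SD of slow vertical gaze noise, deg (the target
#'   moves horizontally only).
#' @param ttc_bias_gain Multiplicative bias on the perceived post-change
#'   speed used to time the TTC button press: 1 is unbiased, > 1 perceives
#'   the target as faster (presses too early), < 1 too late.
#' @param ttc_response_sd SD of the TTC button-press time, s.
#' @param speed_update_time Saccadic-suppression coupling, s: time needed
#'   after the perturbation for the perceived speed to update fully from
#'   the pre-change to the post-change value. With a detection latency
#'   shorter than this, the TTC press extrapolates a blend biased toward
#'   the old speed (early saccades "freeze" the old speed). 0 (default)
#'   disables the coupling: the new speed is always used.
#' @param invalid_trial_rate Probability that a trial carries a slow gaze
#'   drift exceeding the 3 deg validity criterion.
#' @param post_ttc_window Recording time kept after the true TTC, s.
#' @return A list of class `oculomotor_params`.
#' @examples
#' p <- oculomotor_params(miss_rate = 0)
#' p$detection_latency_mean
#' @export
oculomotor_params <- function(sample_rate = 200,
                              pursuit_gain = 0.95,
                              pursuit_latency = 0.15,
                              detection_latency_mean = 0.3,
                              detection_latency_sd = 0.05,
                              miss_rate = 0.05,
                              false_alarm_rate = 0.05,
                              main_sequence_slope = 30,
                              landing_noise_sd = 0.3,
                              fixation_noise_sd = 0.2,
                              pursuit_noise_sd = 0.1,
                              noise_tau = 0.3,
                              measurement_noise_sd = 0.02,
                              vertical_noise_sd = 0.1,
                              ttc_bias_gain = 1.0,
                              ttc_response_sd = 0.2,
                              speed_update_time = 0,
                              invalid_trial_rate = 0.3,
                              post_ttc_window = 1.0) {
  p <- as.list(environment())
  probs <- c(p$miss_rate, p$false_alarm_rate, p$invalid_trial_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("miss_rate, false_alarm_rate and invalid_trial_rate must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$sample_rate <= 0) stop("`sample_rate` must be positive", call. = FALSE)
  if (p$pursuit_latency < 0 || p$detection_latency_mean < 0) {
    stop("latencies must be non-negative", call. = FALSE)
  }
  if (p$main_sequence_slope <= 0) {
    stop("`main_sequence_slope` must be positive", call. = FALSE)
  }
  structure(p, class = "oculomotor_params")
}

# Stationary AR(1) noise: sd is the stationary SD, tau the correlation time.
ar1_noise <- function(n, sd, tau, dt) {
  if (sd <= 0 || n == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + innov[i]
  x
}

# Raised-cosine saccade displacement: amplitude A starting at time 0,
# duration D = 2|A|/Vp with Vp = slope*|A|, i.e. D = 2/slope.
# v(t) = Vp/2 * (1 - cos(2 pi t / D)); integral at D equals |A|.
saccade_displacement <- function(t_rel, amplitude, slope) {
  d <- saccade_duration(slope)
  vp <- slope * abs(amplitude)
  frac <- pmin(pmax(t_rel / d, 0), 1)
  disp <- vp / 2 * (frac * d - d * sin(2 * pi * frac) / (2 * pi))
  sign(amplitude) * disp
}

saccade_duration <- function(slope) 2 / slope

#' Simulate one trial of gaze and response behaviour
#'
#' Generates a ground-truth-labelled gaze recording for one trial: smooth
#' pursuit of the target with gain, latency and slow drift noise; in
#' `mode = "saccade"` (Experiments 1-2) a main-sequence saccade to the
#' fixation cross initiated one detection latency after the speed change,
#' followed by fixation; in `mode = "pursuit"` (Experiment 3) continued
#' pursuit plus a perturbation button press. A TTC button press is emitted
#' at the time the target would reach the cross if it moved at
#' `ttc_bias_gain` times its true post-change speed, plus Gaussian noise.
#'
#' @param timeline A [build_timeline()] object.
#' @param params An [oculomotor_params()] list.
#' @param mode `"saccade"` or `"pursuit"`.
#' @param seed Optional integer; if given the trial is a deterministic
#'   function of it (the caller's RNG state is untouched).
#' @return A list with
#'   * `gaze`: tibble `t`, `x`, `y` (s, deg, deg) sampled uniformly,
#'   * `events`: tibble `time`, `kind` (`"perturbation_response"`,
#'     `"ttc_response"`),
#'   * `truth`: one-row tibble of ground-truth labels (true saccade
#'     interval, detection time, true TTC, intended validity, ...).
#' @examples
#' tl <- build_timeline(trial_design(speed = 3, occlusion = 1.0))
#' sim <- simulate_trial(tl, oculomotor_params(invalid_trial_rate = 0), seed = 1)
#' head(sim$gaze)
#' @export
simulate_trial <- function(timeline, params = oculomotor_params(),
                           mode = c("saccade", "pursuit"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(timeline, "stim_timeline"),
            inherits(params, "oculomotor_params"))
  dt <- 1 / params$sample_rate
  if (saccade_duration(params$main_sequence_slope) < 2 * dt) {
    stop("`sample_rate` too low to represent a saccade of duration ",
         signif(saccade_duration(params$main_sequence_slope), 3), " s",
         call. = FALSE)
  }
  with_rng_seed(seed, simulate_trial_impl(timeline, params, mode, dt))
}

simulate_trial_impl <- function(timeline, params, mode, dt) {
  design <- timeline$design
  perturbation <- design$speed != design$pre_change_speed
  dur <- timeline$ttc + params$post_ttc_window
  t <- seq(0, dur, by = dt)
  n <- length(t)

  # --- latent behavioural draws -------------------------------------------
  detected <- perturbation && runif(1) >= params$miss_rate
  false_alarm <- !perturbation && runif(1) < params$false_alarm_rate
  detection_time <- NA_real_
  if (detected) {
    lat <- max(0.05, rnorm(1, params$detection_latency_mean,
                           params$detection_latency_sd))
    detection_time <- timeline$change_onset + lat
  } else if (false_alarm) {
    detection_time <- timeline$change_onset + runif(1, 0.3, 1.2)
  }
  responds <- !is.na(detection_time)
  make_drift <- runif(1) < params$invalid_trial_rate

  # --- pursuit trajectory (gain + onset latency) --------------------------
  e0 <- design$initial_eccentricity * timeline$side_sign
  t_lag <- pmax(t - params$pursuit_latency, 0)
  x <- e0 + params$pursuit_gain * (target_position(timeline, t_lag) - e0)

  # --- response saccade (saccade mode) ------------------------------------
  sacc_on <- sacc_off <- amplitude <- NA_real_
  if (mode == "saccade" && responds) {
    sacc_on <- detection_time
    sacc_off <- sacc_on + saccade_duration(params$main_sequence_slope)
    pos_on <- approx(t, x, xout = sacc_on, rule = 2)$y
    landing <- rnorm(1, 0, params$landing_noise_sd)
    amplitude <- landing - pos_on
    during <- t >= sacc_on & t < sacc_off
    after <- t >= sacc_off
    x[during] <- pos_on +
      saccade_displacement(t[during] - sacc_on, amplitude,
                           params$main_sequence_slope)
    x[after] <- pos_on + amplitude
  }

  # --- slow drift making the trial invalid --------------------------------
  intended_valid <- !make_drift
  if (make_drift) {
    drift_end <- min(timeline$occlusion_time,
                     if (!is.na(sacc_on)) sacc_on else Inf)
    # peak chosen so the drift exceeds the 3 deg criterion even when it
    # opposes the pursuit lag (lag can offset up to ~1 deg)
    peak <- runif(1, 4.5, 6) * sample(c(-1, 1), 1)
    ramp <- pmin(pmax((t - timeline$motion_onset) /
                        (drift_end - timeline$motion_onset), 0), 1)
    if (!is.na(sacc_on)) ramp[t >= sacc_on] <- 0 # saccade lands on the cross
    x <- x + peak * ramp
  }

  # --- oculomotor + tracker noise -----------------------------------------
  slow_sd <- if (mode == "saccade" && responds) {
    ifelse(t < sacc_on, params$pursuit_noise_sd, params$fixation_noise_sd)
  } else rep(params$pursuit_noise_sd, n)
  slow <- ar1_noise(n, 1, params$noise_tau, dt) * slow_sd
  x <- x + slow + rnorm(n, 0, params$measurement_noise_sd)
  y <- ar1_noise(n, params$vertical_noise_sd, params$noise_tau, dt) +
    rnorm(n, 0, params$measurement_noise_sd)

  # --- button responses ----------------------------------------------------
  events <- tibble(time = numeric(), kind = character())
  if (mode == "pursuit" && responds) {
    events <- bind_rows(events,
                        tibble(time = detection_time, kind = "perturbation_response"))
  }
  # perceived post-change speed: optionally blended toward the pre-change
  # speed when the response was initiated before the percept updated
  perceived <- design$speed
  if (params$speed_update_time > 0 && perturbation && detected) {
    lat_frac <- min(1, (detection_time - timeline$change_onset) /
                      params$speed_update_time)
    perceived <- design$pre_change_speed +
      (design$speed - design$pre_change_speed) * lat_frac
  }
  ttc_press <- timeline$change_onset +
    timeline$ecc_at_change / (perceived * params$ttc_bias_gain) +
    rnorm(1, 0, params$ttc_response_sd)
  events <- bind_rows(events, tibble(time = ttc_press, kind = "ttc_response"))

  truth <- tibble(
    trial_id = design$trial_id, mode = mode,
    perturbation = perturbation, detected = detected,
    false_alarm = false_alarm, detection_time = detection_time,
    sacc_onset = sacc_on, sacc_offset = sacc_off, sacc_amplitude = amplitude,
    change_onset = timeline$change_onset,
    occlusion_time = timeline$occlusion_time,
    true_ttc = timeline$ttc, ttc_press = ttc_press,
    intended_valid = intended_valid
  )
  list(gaze = tibble(t = t, x = x, y = y), events = events, truth = truth)
}

#' Simulate a cohort of participants over an experiment design
#'
#' Runs [simulate_trial()] for every participant x trial combination and
#' binds the results into long tibbles. One `oculomotor_params` object may
#' be shared by all participants or supplied per participant.
#'
#' @param design A design tibble from [generate_design()] (or any design
#'   tibble with one row per trial).
#' @param params A single [oculomotor_params()] object or a named list of
#'   one per participant (names become participant ids).
#' @param n_participants Number of participants when `params` is a single
#'   object.
#' @param mode Passed to [simulate_trial()].
#' @param seed Integer seed for the whole cohort.
#' @return A list of tibbles `gaze` (participant, trial_id, t, x, y),
#'   `events` (participant, trial_id, time, kind) and `truth` (one row per
#'   participant x trial, with the design columns joined in).
#' @export
simulate_cohort <- function(design, params = oculomotor_params(),
                            n_participants = 1,
                            mode = c("saccade", "pursuit"), seed = 1) {
  mode <- match.arg(mode)
  design <- fill_design_defaults(design)
  validate_design(design)
  if (inherits(params, "oculomotor_params")) {
    params <- setNames(rep(list(params), n_participants),
                       paste0("P", seq_len(n_participants)))
  }
  if (is.null(names(params)) || anyDuplicated(names(params))) {
    stop("participant ids (names of `params`) must be unique", call. = FALSE)
  }
  with_rng_seed(seed, {
    out <- purrr::imap(params, function(pp, pid) {
      trials <- purrr::map(seq_len(nrow(design)), function(i) {
        tl <- build_timeline(design[i, ])
        sim <- simulate_trial_impl(tl, pp, mode, 1 / pp$sample_rate)
        sim$gaze$trial_id <- design$trial_id[i]
        sim$events$trial_id <- design$trial_id[i]
        sim
      })
      list(
        gaze = bind_rows(purrr::map(trials, "gaze")) %>%
          mutate(participant = pid, .before = 1),
        events = bind_rows(purrr::map(trials, "events")) %>%
          mutate(participant = pid, .before = 1),
        truth = bind_rows(purrr::map(trials, "truth")) %>%
          mutate(participant = pid, .before = 1)
      )
    })
    list(
      gaze = bind_rows(purrr::map(out, "gaze")),
      events = bind_rows(purrr::map(out, "events")),
      truth = bind_rows(purrr::map(out, "truth")) %>%
        left_join(design %>% select("trial_id", "speed", "occlusion", "side"),
                  by = "trial_id")
    )
  })
}
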