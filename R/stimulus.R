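#' Trial design for the occluded speed-perturbation paradigm
#'
#' One trial of the paradigm: a circle appears at `initial_eccentricity`
#' degrees to the left or right of a central fixation cross, starts to move
#' toward the cross after `pre_motion` seconds at `pre_change_speed` deg/s,
#' and after `pre_change_duration` seconds either keeps its speed (catch
#' trial) or steps to `speed` deg/s (perturbation). `occlusion` seconds after
#' the speed-change onset the circle disappears but keeps moving until (and
#' past) the moment its centre coincides with the cross (the time to contact,
#' TTC).
#'
#' All positions are signed degrees of visual angle on a horizontal axis with
#' the cross at the origin; positive values lie toward the target's start
#' side. Degrees and seconds are the canonical units; screen millimetres are
#' available as a view via [deg_to_mm()].
#'
#' @param speed Target speed after the change onset, deg/s (3, 4 or 5 in the
#'   reference design; 4 means no perturbation).
#' @param occlusion Delay between speed-change onset and target occlusion, s.
#' @param side `"right"` or `"left"`: side of the cross on which the target
#'   appears.
#' @param pre_motion Stationary period before motion onset, s.
#' @param pre_change_speed Speed between motion onset and change onset, deg/s.
#' @param pre_change_duration Duration of the pre-change motion, s.
#' @param initial_eccentricity Target eccentricity at appearance, deg.
#' @return A one-row tibble with the design factors; feed it (or a many-row
#'   design from [generate_design()]) to [build_timeline()],
#'   [eccentricity_at_occlusion()] and friends.
#' @examples
#' trial_design(speed = 3, occlusion = 1.0)
#' @export
trial_design <- function(speed = 4, occlusion = 1.0,
                         side = c("right", "left"),
                         pre_motion = 1.0, pre_change_speed = 4.0,
                         pre_change_duration = 1.0,
                         initial_eccentricity = 14.0) {
  side <- match.arg(side)
  design <- tibble(
    trial_id = 1L, speed = speed, occlusion = occlusion, side = side,
    pre_motion = pre_motion, pre_change_speed = pre_change_speed,
    pre_change_duration = pre_change_duration,
    initial_eccentricity = initial_eccentricity
  )
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design), nrow(design) >= 1)
  needed <- c("speed", "occlusion", "side")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  design <- fill_design_defaults(design)
  if (any(design$speed <= 0)) {
    stop("`speed` must be positive (post-change target speed, deg/s)",
         call. = FALSE)
  }
  if (any(design$occlusion <= 0)) {
    stop("`occlusion` must be positive (delay after change onset, s)",
         call. = FALSE)
  }
  if (any(design$pre_change_speed <= 0)) {
    stop("`pre_change_speed` must be positive", call. = FALSE)
  }
  if (!all(design$side %in% c("left", "right"))) {
    stop("`side` must be \"left\" or \"right\"", call. = FALSE)
  }
  invisible(design)
}

# Optional geometry columns default to the reference design.
fill_design_defaults <- function(design) {
  defaults <- list(pre_motion = 1.0, pre_change_speed = 4.0,
                   pre_change_duration = 1.0, initial_eccentricity = 14.0)
  for (nm in names(defaults)) {
    if (!nm %in% names(design)) design[[nm]] <- defaults[[nm]]
  }
  if (!"trial_id" %in% names(design)) design$trial_id <- seq_len(nrow(design))
  design
}

# Eccentricity at speed-change onset (10 deg under the reference design).
ecc_at_change <- function(design) {
  design$initial_eccentricity - design$pre_change_speed * design$pre_change_duration
}

#' Event times and target kinematics for one trial
#'
#' Builds the piecewise-linear target trajectory for a single trial design:
#' the target is stationary until `motion_onset`, moves at the pre-change
#' speed until `change_onset`, then at the (possibly perturbed) post-change
#' speed; it is occluded at `occlusion_time` but continues to move, reaching
#' the cross centre exactly at `ttc`.
#'
#' @param design A one-row design tibble (see [trial_design()]).
#' @return A `stim_timeline` object: event times (s, trial clock with target
#'   appearance at 0) plus the design row. Query it with [target_position()]
#'   and [target_visible()].
#' @examples
#' tl <- build_timeline(trial_design(speed = 3, occlusion = 1.0))
#' tl$ttc - tl$change_onset # 10/3 s
#' target_position(tl, tl$ttc) # 0 at contact
#' @export
build_timeline <- function(design) {
  design <- fill_design_defaults(design)
  if (nrow(design) != 1) {
    stop("`build_timeline()` expects a one-row design; got ", nrow(design),
         " rows (use lapply/purrr::pmap for many trials)", call. = FALSE)
  }
  validate_design(design)
  e_c <- ecc_at_change(design)
  if (e_c <= 0) {
    stop("`initial_eccentricity` must exceed the pre-change travel ",
         "(eccentricity at change onset is ", e_c, " deg)", call. = FALSE)
  }
  motion_onset <- design$pre_motion
  change_onset <- motion_onset + design$pre_change_duration
  structure(
    list(
      appearance = 0,
      motion_onset = motion_onset,
      change_onset = change_onset,
      occlusion_time = change_onset + design$occlusion,
      ttc = change_onset + e_c / design$speed,
      ecc_at_change = e_c,
      side_sign = if (design$side == "left") -1 else 1,
      design = design
    ),
    class = "stim_timeline"
  )
}

#' @export
print.stim_timeline <- function(x, ...) {
  cat("<stim_timeline>\n")
  cat(sprintf("  speed %.3g deg/s after change, occlusion %+.3g s, side %s\n",
              x$design$speed, x$design$occlusion, x$design$side))
  cat(sprintf("  motion onset %.2f s | change onset %.2f s | occluded %.2f s | TTC %.3f s\n",
              x$motion_onset, x$change_onset, x$occlusion_time, x$ttc))
  invisible(x)
}

#' Signed target position relative to the cross
#'
#' @param timeline A [build_timeline()] object.
#' @param t Time(s) on the trial clock, s.
#' @param signed If `TRUE` (default) the position carries the start-side sign
#'   (positive toward the start side); if `FALSE` the unsigned distance-to-go
#'   is returned (positive until contact, negative after).
#' @return Position in degrees of visual angle; 0 exactly at TTC. Defined for
#'   all `t`, including after occlusion (the target keeps moving unseen).
#' @export
target_position <- function(timeline, t, signed = TRUE) {
  d <- timeline$design
  pos <- ifelse(
    t <= timeline$motion_onset,
    d$initial_eccentricity,
    ifelse(
      t <= timeline$change_onset,
      d$initial_eccentricity - d$pre_change_speed * (t - timeline$motion_onset),
      timeline$ecc_at_change - d$speed * (t - timeline$change_onset)
    )
  )
  if (signed) pos * timeline$side_sign else pos
}

#' @rdname target_position
#' @export
target_visible <- function(timeline, t) {
  t < timeline$occlusion_time
}

#' Table-1-style analytic quantities of a design
#'
#' `eccentricity_at_occlusion()` is the angular distance between target and
#' cross at the moment of occlusion; `time_to_ttc_from_occlusion()` the time
#' the (now invisible) target still needs to reach the cross; and
#' `peripheral_monitoring_time()` the time the visible target can be
#' monitored peripherally after the response saccade lands, assuming the
#' saccade is initiated `assumed_latency` seconds after the perturbation.
#' All are vectorized over the rows of a design tibble.
#'
#' @param design Design tibble (one or more rows).
#' @param assumed_latency Assumed saccadic response latency, s (0.3 in the
#'   reference analysis).
#' @return Numeric vector, one value per design row (deg or s).
#' @examples
#' d <- trial_design(speed = 3, occlusion = 0.3)
#' eccentricity_at_occlusion(d) # 9.1
#' time_to_ttc_from_occlusion(d) # 3.033
#' @export
eccentricity_at_occlusion <- function(design) {
  design <- fill_design_defaults(design)
  validate_design(design)
  ecc <- ecc_at_change(design) - design$speed * design$occlusion
  if (any(ecc <= 0)) {
    bad <- which(ecc <= 0)[1]
    stop("invalid geometry: target would reach the cross before occlusion ",
         "(speed ", design$speed[bad], " deg/s, occlusion ",
         design$occlusion[bad], " s)", call. = FALSE)
  }
  ecc
}

#' @rdname eccentricity_at_occlusion
#' @export
time_to_ttc_from_occlusion <- function(design) {
  eccentricity_at_occlusion(design) / fill_design_defaults(design)$speed
}

#' @rdname eccentricity_at_occlusion
#' @export
peripheral_monitoring_time <- function(design, assumed_latency = 0.3) {
  stopifnot(assumed_latency >= 0)
  design <- fill_design_defaults(design)
  validate_design(design)
  pmax(0, design$occlusion - assumed_latency)
}

#' Analytic stimulus table across all speed x occlusion combinations
#'
#' Reproduces, from the kinematic model alone, the per-condition table of
#' eccentricity at occlusion, remaining time to TTC, and approximate
#' peripheral monitoring time for the reference design (speeds 3/4/5 deg/s;
#' occlusion delays 0.3-1.5 s), rounded as conventionally printed.
#'
#' @param speeds Post-change speeds, deg/s.
#' @param occlusions Occlusion delays, s.
#' @param assumed_latency Assumed saccadic latency for monitoring time, s.
#' @return A tibble with one row per speed x occlusion combination:
#'   `speed`, `occlusion_ms`, `eccentricity_deg` (1 decimal),
#'   `time_to_ttc_s` (2 decimals), `monitoring_s` (1 decimal).
#' @examples
#' stimulus_table()
#' @export
stimulus_table <- function(speeds = c(3, 4, 5),
                           occlusions = c(0.3, 0.5, 0.7, 0.9, 1.0, 1.5),
                           assumed_latency = 0.3) {
  grid <- tidyr::expand_grid(speed = speeds, occlusion = occlusions)
  grid$side <- "right"
  tibble(
    speed = grid$speed,
    occlusion_ms = round(grid$occlusion * 1000),
    eccentricity_deg = round(eccentricity_at_occlusion(grid), 1),
    time_to_ttc_s = round(time_to_ttc_from_occlusion(grid), 2),
    monitoring_s = round(peripheral_monitoring_time(grid, assumed_latency), 1)
  )
}

#' Quasi-randomized factorial experiment designs
#'
#' Generates the trial list of one of the three reference experiments in a
#' quasi-randomized order: trial order is shuffled under the constraint that
#' the same speed condition never occurs more than `max_run` times in a row.
#'
#' * Experiment 1: 40 trials per speed (3/4/5 deg/s) x occlusion (1.0/1.5 s)
#'   cell, 240 trials.
#' * Experiments 2 and 3: occlusions 0.3/0.5/0.7/0.9 s with 30 trials per
#'   cell for the perturbation speeds (3 and 5 deg/s) and 10 per cell for the
#'   4 deg/s catch trials, 280 trials.
#'
#' @param experiment 1, 2 or 3.
#' @param seed Integer seed; the design is a deterministic function of it.
#' @param cells Optional custom design: a tibble with columns `speed`,
#'   `occlusion`, `n` overriding the built-in cell counts.
#' @param max_run Maximum run length of a single speed condition.
#' @param max_tries Restart budget for the constrained shuffle.
#' @return A design tibble (one row per trial, in presentation order) with
#'   columns `trial_id`, `speed`, `occlusion`, `side` and the geometry
#'   defaults.
#' @examples
#' d <- generate_design(1, seed = 1)
#' nrow(d) # 240
#' @export
generate_design <- function(experiment = 1, seed = 1, cells = NULL,
                            max_run = 3, max_tries = 200) {
  if (is.null(cells)) {
    stopifnot(experiment %in% 1:3)
    cells <- if (experiment == 1) {
      tidyr::expand_grid(speed = c(3, 4, 5), occlusion = c(1.0, 1.5)) %>%
        mutate(n = 40L)
    } else {
      tidyr::expand_grid(speed = c(3, 4, 5), occlusion = c(0.3, 0.5, 0.7, 0.9)) %>%
        mutate(n = if_else(.data$speed == 4, 10L, 30L))
    }
  }
  stopifnot(all(c("speed", "occlusion", "n") %in% names(cells)))
  with_rng_seed(seed, {
    speeds <- order_speeds_constrained(
      rep(cells$speed, cells$n), max_run = max_run, max_tries = max_tries
    )
    # Distribute each speed's occlusion cells (and balanced sides) randomly
    # over that speed's slots in the sequence.
    design <- tibble(trial_id = seq_along(speeds), speed = speeds,
                     occlusion = NA_real_, side = NA_character_)
    for (sp in unique(cells$speed)) {
      sub <- cells[cells$speed == sp, ]
      occl <- rep(sub$occlusion, sub$n)
      sides <- rep_len(c("right", "left"), length(occl))
      slots <- which(speeds == sp)
      perm <- sample.int(length(slots))
      design$occlusion[slots] <- occl[perm]
      design$side[slots] <- sample(sides)[perm]
    }
    fill_design_defaults(design)
  })
}

# Random order of a speed multiset with no run longer than max_run.
# Sequential sampling proportional to remaining counts, restarting on dead
# ends (a plain shuffle almost always violates the constraint at these n).
order_speeds_constrained <- function(speeds, max_run = 3, max_tries = 200) {
  counts0 <- table(speeds)
  levels <- as.numeric(names(counts0))
  for (try in seq_len(max_tries)) {
    counts <- as.vector(counts0)
    out <- numeric(length(speeds))
    run_val <- NA_real_; run_len <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      allowed <- counts > 0
      if (run_len >= max_run) allowed <- allowed & (levels != run_val)
      if (!any(allowed)) { ok <- FALSE; break }
      pick <- sample(seq_along(levels), 1, prob = counts * allowed)
      out[i] <- levels[pick]
      counts[pick] <- counts[pick] - 1L
      if (identical(levels[pick], run_val)) run_len <- run_len + 1L
      else { run_val <- levels[pick]; run_len <- 1L }
    }
    if (ok) return(out)
  }
  stop("could not order trials with max run length ", max_run, " in ",
       max_tries, " attempts; the cell counts may make it infeasible",
       call. = FALSE)
}

#' Longest run of a single speed condition
#'
#' @param design A design tibble in presentation order.
#' @return Integer: maximum number of consecutive trials sharing a speed.
#' @export
max_speed_run <- function(design) {
  max(rle(design$speed)$lengths)
}

#' Degrees of visual angle to screen millimetres (and back)
#'
#' Exact tangent conversion for a flat screen viewed frontally at
#' `viewing_distance` metres: `mm = 1000 * d * tan(angle)`.
#'
#' @param angle Angle(s), degrees of visual angle; |angle| < 90.
#' @param mm Screen offset(s) from the line of sight, mm.
#' @param viewing_distance Eye-to-screen distance, m.
#' @return Millimetres (`deg_to_mm`) or degrees (`mm_to_deg`).
#' @examples
#' deg_to_mm(30) # 692.8 mm at 1.2 m
#' mm_to_deg(deg_to_mm(7)) # 7
#' @export
deg_to_mm <- function(angle, viewing_distance = 1.2) {
  stopifnot(all(abs(angle) < 90))
  1000 * viewing_distance * tan(angle * pi / 180)
}

#' @rdname deg_to_mm
#' @export
mm_to_deg <- function(mm, viewing_distance = 1.2) {
  atan(mm / (1000 * viewing_distance)) * 180 / pi
}

# Evaluate expr under a temporary, restorable RNG state.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
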