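#' Eye velocity from a gaze recording
#'
#' Differentiates the gaze position signal by central differences and
#' smooths the velocity components with a zero-phase (forward-backward)
#' second-order Butterworth low-pass filter at `cutoff` Hz. Zero-phase
#' filtering keeps event times unbiased; the filter has unit DC gain, so
#' constant velocities (ramps in position) pass through unchanged. The
#' signal is reflection-padded before filtering to suppress edge
#' transients.
#'
#' @param gaze Tibble with columns `t` (s, uniformly sampled), `x`, `y`
#'   (deg). A missing `y` is treated as 0.
#' @param cutoff Low-pass cutoff frequency, Hz; `Inf` disables smoothing
#'   (also disabled automatically when the Nyquist frequency is below the
#'   cutoff).
#' @param tol Relative tolerance on sampling-interval uniformity.
#' @return A tibble `t`, `x`, `y`, `vx`, `vy`, `speed` where `speed` is the
#'   2-D velocity magnitude (deg/s).
#' @examples
#' g <- tibble::tibble(t = seq(0, 1, by = 0.005), x = 4 * t, y = 0)
#' v <- compute_velocity(g)
#' range(v$speed[10:190]) # ~4 deg/s throughout
#' @export
compute_velocity <- function(gaze, cutoff = 60, tol = 1e-6) {
  check_columns(gaze, c("t", "x"), "gaze")
  if (!"y" %in% names(gaze)) gaze$y <- 0
  n <- nrow(gaze)
  if (n < 5) stop("need at least 5 samples to estimate velocity", call. = FALSE)
  dts <- diff(gaze$t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > tol * max(dt, 1e-12))) {
    stop("gaze timestamps are not uniformly sampled (max deviation ",
         signif(max(abs(dts - dt)), 3), " s)", call. = FALSE)
  }
  vx <- central_diff(gaze$x, dt)
  vy <- central_diff(gaze$y, dt)
  fs <- 1 / dt
  if (is.finite(cutoff) && cutoff < fs / 2) {
    vx <- lowpass_zerophase(vx, fs, cutoff)
    vy <- lowpass_zerophase(vy, fs, cutoff)
  }
  tibble(t = gaze$t, x = gaze$x, y = gaze$y, vx = vx, vy = vy,
         speed = sqrt(vx^2 + vy^2))
}

central_diff <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

# Forward-backward 2nd-order Butterworth with odd (point-symmetric)
# reflection padding at both ends, as is conventional for zero-phase
# filtering of finite records.
lowpass_zerophase <- function(x, fs, cutoff, order = 2) {
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2))
  pad <- min(n - 1, max(12, ceiling(0.05 * fs)))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Velocity-threshold saccade detection
#'
#' Detects saccades as maximal runs of samples whose (filtered) eye speed
#' exceeds a fixed velocity threshold of 22 deg/s. Runs separated by less
#' than `merge_gap` are merged, then runs shorter than `min_duration` are
#' discarded. The onset is the time of the first supra-threshold sample and
#' the offset that of the last.
#'
#' @param velocity Output of [compute_velocity()].
#' @param threshold Velocity threshold, deg/s.
#' @param min_duration Minimum saccade duration (onset-to-offset span), s.
#' @param merge_gap Runs closer than this are considered one saccade, s.
#' @return A tibble with one row per saccade: `onset`, `offset`, `duration`
#'   (s), `peak_speed` (deg/s) and, when positions are present, `amplitude`
#'   (deg, 2-D displacement from onset to offset sample).
#' @export
detect_saccades <- function(velocity, threshold = 22, min_duration = 0.010,
                            merge_gap = 0.020) {
  check_columns(velocity, c("t", "speed"), "velocity")
  above <- velocity$speed > threshold
  runs <- run_bounds(above)
  empty <- tibble(onset = numeric(), offset = numeric(), duration = numeric(),
                  amplitude = numeric(), peak_speed = numeric())
  if (nrow(runs) == 0) return(empty)
  tt <- velocity$t
  # merge runs separated by < merge_gap
  keep <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      prev <- keep[[length(keep)]]
      if (tt[runs$start[i]] - tt[prev$end] < merge_gap) {
        prev$end <- runs$end[i]
        keep[[length(keep)]] <- prev
      } else keep[[length(keep) + 1]] <- runs[i, ]
    }
  }
  runs <- bind_rows(keep)
  out <- tibble(
    onset = tt[runs$start], offset = tt[runs$end],
    duration = tt[runs$end] - tt[runs$start],
    amplitude = if (all(c("x", "y") %in% names(velocity))) {
      sqrt((velocity$x[runs$end] - velocity$x[runs$start])^2 +
             (velocity$y[runs$end] - velocity$y[runs$start])^2)
    } else NA_real_,
    peak_speed = purrr::map2_dbl(runs$start, runs$end,
                                 ~max(velocity$speed[.x:.y]))
  )
  out[out$duration >= min_duration, ]
}

run_bounds <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Pursuit-eligible sample mask
#'
#' Marks the samples usable for pursuit-velocity statistics: everything
#' outside any detected saccade extended by an exclusion margin of 16 ms
#' before onset and 70 ms after offset.
#'
#' @param velocity Output of [compute_velocity()] (only `t` is used).
#' @param saccades Output of [detect_saccades()].
#' @param pre_margin,post_margin Exclusion margins, s.
#' @return Logical vector, `TRUE` where the sample counts as pursuit.
#' @export
pursuit_mask <- function(velocity, saccades, pre_margin = 0.016,
                         post_margin = 0.070) {
  check_columns(velocity, "t", "velocity")
  mask <- rep(TRUE, nrow(velocity))
  for (i in seq_len(nrow(saccades))) {
    mask[velocity$t >= saccades$onset[i] - pre_margin &
           velocity$t <= saccades$offset[i] + post_margin] <- FALSE
  }
  mask
}

#' Per-sample gaze-target and gaze-cross distances
#'
#' Euclidean angular distance between the gaze point and (a) the target
#' circle's centre -- defined at every sample, also while the target is
#' occluded -- and (b) the fixation cross at the origin.
#'
#' @param gaze Tibble with `t`, `x` and optionally `y` (deg).
#' @param timeline The trial's [build_timeline()] object (shares the trial
#'   clock with the recording).
#' @return A tibble `t`, `dist_circle`, `dist_cross`, `target_visible`.
#' @export
distance_series <- function(gaze, timeline) {
  check_columns(gaze, c("t", "x"), "gaze")
  if (!"y" %in% names(gaze)) gaze$y <- 0
  tp <- target_position(timeline, gaze$t)
  tibble(
    t = gaze$t,
    dist_circle = sqrt((gaze$x - tp)^2 + gaze$y^2),
    dist_cross = sqrt(gaze$x^2 + gaze$y^2),
    target_visible = target_visible(timeline, gaze$t)
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("`", what, "` is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
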