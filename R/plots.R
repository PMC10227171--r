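#' Space-time plot of one trial's stimulus
#'
#' @param object A [build_timeline()] object.
#' @param ... Unused.
#' @return A ggplot: signed target position against time, with the
#'   occluded part dashed and the event times marked.
#' @export
autoplot.stim_timeline <- function(object, ...) {
  t <- seq(0, object$ttc + 0.5, length.out = 400)
  df <- tibble(t = t, position = target_position(object, t),
               visible = target_visible(object, t))
  events <- tibble(
    time = c(object$motion_onset, object$change_onset,
             object$occlusion_time, object$ttc),
    event = factor(c("motion onset", "change onset", "occlusion", "TTC"),
                   levels = c("motion onset", "change onset", "occlusion", "TTC"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$position)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$visible)) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"), guide = "none") +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$time,
                                     colour = .data$event),
                        linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "target position (deg, cross at 0)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Eye-speed trace with detected saccades
#'
#' @param velocity Output of [compute_velocity()].
#' @param saccades Optional [detect_saccades()] table to shade.
#' @param threshold Velocity threshold to draw, deg/s.
#' @return A ggplot of eye speed over time.
#' @export
plot_velocity <- function(velocity, saccades = NULL, threshold = 22) {
  p <- ggplot2::ggplot(velocity, ggplot2::aes(x = .data$t, y = .data$speed)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "eye speed (deg/s)") +
    ggplot2::theme_minimal()
  if (!is.null(saccades) && nrow(saccades) > 0) {
    p <- p + ggplot2::geom_rect(
      data = saccades, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Condition summary plot of an aggregate score table
#'
#' Medians with interquartile boxes per speed x occlusion cell, the way
#' prediction-motion results are conventionally displayed.
#'
#' @param aggregate Output of [aggregate_scores()].
#' @param measure Column to plot.
#' @return A ggplot.
#' @export
plot_scores <- function(aggregate, measure = "percent_correct") {
  check_columns(aggregate, c("speed", "occlusion", measure), "aggregate")
  ggplot2::ggplot(aggregate,
                  ggplot2::aes(x = factor(.data$occlusion),
                               y = .data[[measure]],
                               fill = factor(.data$speed))) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::labs(x = "occlusion delay (s)", y = measure,
                  fill = "speed (deg/s)") +
    ggplot2::theme_minimal()
}
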