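#' Plot a recording or clean trace
#'
#' Gaze and target position over time along the task axis; invalid
#' samples (blinks, artifacts) are left blank.
#'
#' @param object A `vog_trace` (or `vog_recording`; raw recordings show
#'   the left eye).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vog_trace <- function(object, ...) {
  axis <- trace_axis(object)
  df <- tibble(
    time = object$time_s,
    gaze = if (axis == "horizontal") object$gaze_h else object$gaze_v,
    target = if (axis == "horizontal") object$target_h else object$target_v
  )
  df$gaze[!object$valid] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$target), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$gaze), colour = "#2166ac") +
    ggplot2::labs(x = "Time (s)", y = sprintf("%s position (deg)", axis),
                  title = attr(object, "paradigm")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vog_recording <- function(object, ...) {
  axis <- if (!is.null(attr(object, "protocol")))
    attr(object, "protocol")$axis else "horizontal"
  gaze <- if (axis == "horizontal") object$left_h_deg else object$left_v_deg
  gaze[abs(gaze) > 60] <- NA
  df <- tibble(
    time = object$time_s, gaze = gaze,
    target = if (axis == "horizontal") object$target_h_deg
    else object$target_v_deg
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$target), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$gaze), colour = "#b2182b") +
    ggplot2::labs(x = "Time (s)", y = sprintf("%s position (deg)", axis),
                  title = paste(attr(object, "paradigm"), "(left eye, raw)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vog_main_sequence <- function(object, ...) {
  grid <- tibble(amplitude = seq(0.5, max(object$data$amplitude) * 1.05,
                                 length.out = 200))
  grid$v <- evaluate_at(object, grid$amplitude)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$amplitude,
                               y = .data$peak_velocity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$v),
                       colour = "#2166ac") +
    ggplot2::labs(x = "Amplitude (deg)", y = "Peak velocity (deg/s)",
                  title = sprintf("Main sequence: vmax = %.0f deg/s, c = %.1f deg",
                                  object$vmax, object$c)) +
    ggplot2::theme_minimal()
}

#' Staging scatter of a parameter against its control fence
#'
#' One jittered point per subject, grouped by assigned stage, with the
#' control-derived Tukey fence drawn as a red line in the parameter's
#' abnormal direction.
#'
#' @param staged Output of [stage_cohort()] (needs `stage` and the
#'   parameter column).
#' @param reference The `vog_reference` used for staging.
#' @param parameter Parameter to display.
#' @return A ggplot object.
#' @export
plot_staging <- function(staged, reference, parameter) {
  f <- fence_row(reference, parameter)
  fence <- if (nrow(f) == 1 && f$abnormal_direction == "low")
    f$lower_fence else f$upper_fence
  df <- tibble(stage = staged$stage, value = staged[[parameter]])
  df <- filter(df, is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7,
                         ggplot2::aes(colour = .data$stage)) +
    ggplot2::geom_hline(yintercept = fence, colour = "#b2182b") +
    ggplot2::labs(x = NULL, y = parameter,
                  title = sprintf("%s (fence at %.3g)", parameter, fence)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
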