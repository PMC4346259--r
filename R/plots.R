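#' Plot methods for tiderisk result objects
#'
#' `autoplot()` methods give quick diagnostic figures: yearly expected
#' losses per setting for a risk report, activity against current speed
#' for a (synthetic or read-in) field study, a tornado-style bar chart
#' for a one-at-a-time sensitivity table, and the fitted probability
#' curve with its breaking point for a logistic threshold model.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-tiderisk
NULL

#' @rdname autoplot-tiderisk
#' @exportS3Method ggplot2::autoplot
autoplot.risk_report <- function(object, ...) {
  d <- dplyr::filter(object, .data$label != "total")
  d$label <- factor(d$label, levels = d$label)
  ggplot(d, aes(x = .data$label, y = .data$yearly_n_tm, fill = .data$light)) +
    geom_col() +
    labs(
      x = NULL, y = "Expected yearly losses (individuals)",
      fill = "Light",
      title = "Expected turbine mortality by setting"
    )
}

#' @rdname autoplot-tiderisk
#' @exportS3Method ggplot2::autoplot
autoplot.field_study <- function(object, ...) {
  ggplot(object$samples, aes(x = .data$current_speed, y = .data$activity)) +
    geom_point() +
    labs(
      x = "Current speed (m/s)",
      y = expression("Activity (fish" ~ m^-2 ~ "per sample)"),
      title = "Fish activity over current speed"
    )
}

#' @rdname autoplot-tiderisk
#' @exportS3Method ggplot2::autoplot
autoplot.oat_sensitivity <- function(object, ...) {
  ggplot(
    object,
    aes(x = .data$parameter, y = .data$pct_change, fill = .data$direction)
  ) +
    geom_col(position = position_dodge()) +
    geom_hline(yintercept = 0) +
    labs(
      x = "Parameter", y = "Change in avoidance failure (%)",
      fill = expression(paste(" ", phantom(0))),
      title = "One-at-a-time sensitivity (+/-50%)"
    )
}

#' @rdname autoplot-tiderisk
#' @exportS3Method ggplot2::autoplot
autoplot.logistic_threshold <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    current_speed = seq(min(d$current_speed), max(d$current_speed),
      length.out = 200
    )
  )
  grid$p <- stats::predict(object$fit, newdata = grid, type = "response")
  p <- ggplot(grid, aes(x = .data$current_speed, y = .data$p)) +
    geom_line() +
    geom_point(
      data = d, aes(y = .data$y),
      alpha = 0.2
    ) +
    geom_hline(yintercept = 0.5, linetype = "dotted") +
    labs(
      x = "Current speed (m/s)",
      y = sprintf("P(%s)", object$event),
      title = sprintf("Logistic threshold model: %s", object$outcome)
    )
  if (!is.na(object$breaking_point)) {
    p <- p + geom_vline(xintercept = object$breaking_point, linetype = "dashed")
  }
  p
}
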