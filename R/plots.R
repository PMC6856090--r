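# ggplot2 displays for agreement results and extracted signals.

#' @describeIn roc_analysis ROC curve with the chosen operating point.
#' @param object A `roc_analysis`.
#' @export
autoplot.roc_analysis <- function(object, ...) {
  pts <- object$points
  op <- tibble::tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = op, ggplot2::aes(x = .data$fpr, y = .data$tpr),
                        colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f), cutoff %.2f", object$auc, object$chosen_cutoff)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @describeIn bland_altman Bland-Altman plot with bias and limits of
#'   agreement.
#' @param object A `bland_altman`.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$mean_difference, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Mean of paired measurements", y = "Difference",
      title = sprintf("Bland-Altman: bias %.2f [%.2f, %.2f]",
                      object$mean_difference, object$loa_lower, object$loa_upper)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a stretch of the breathing signal with its envelope
#'
#' @param analysis A [analyze_night()] result.
#' @param from,to Time window, s (defaults to the first 10 minutes).
#' @return A ggplot.
#' @export
plot_breathing <- function(analysis, from = 0, to = 600) {
  br <- analysis$signals$breathing
  df <- dplyr::mutate(br, envelope = analysis$envelope)
  df <- df[df$time >= from & df$time <= to, , drop = FALSE]
  ev <- analysis$respiratory_events
  ev <- ev[ev$onset + ev$duration >= from & ev$onset <= to, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope), colour = "steelblue") +
    ggplot2::labs(x = "Time (s)", y = "Thoracic elevation (mm)",
                  title = "Breathing signal and envelope") +
    ggplot2::theme_minimal()
  if (nrow(ev) > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = ev$onset, xmax = ev$onset + ev$duration,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red"
    )
  }
  p
}
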