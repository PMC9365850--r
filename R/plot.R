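# Optional figures (requires ggplot2; off the default code paths).

#' Plot a timeline result
#'
#' Trend curve with its pointwise confidence band over the annual data, with
#' significant gradient/curvature periods marked along the bottom, in the
#' style of the published timeline panels.
#'
#' @param result a `timeline_result` from [run_timeline()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_timeline <- function(result, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_timeline requires the ggplot2 package")
  }
  curve <- result$bands[result$bands$attribute == "curve", ]
  d <- result$fit$data
  per <- result$periods
  gg <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), linewidth = 0.8) +
    ggplot2::geom_point(data = d, ggplot2::aes(x = .data$year, y = .data$value),
                        size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "Year", y = "Annual value", title = title) +
    ggplot2::theme_minimal()
  if (nrow(per)) {
    ymin <- min(curve$low, d$value)
    per$y <- ymin - 0.04 * diff(range(curve$high, d$value)) *
      as.integer(factor(per$attribute, c("gradient", "curvature")))
    gg <- gg + ggplot2::geom_segment(
      data = per,
      ggplot2::aes(x = .data$start_year, xend = .data$end_year,
                   y = .data$y, yend = .data$y, colour = .data$sign),
      linewidth = 2, inherit.aes = FALSE)
  }
  gg
}
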