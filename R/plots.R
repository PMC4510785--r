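#' Plot a cost-effectiveness plane
#'
#' Scatter of bootstrap incremental cost/QALY pairs with willingness-to-pay
#' rays. Requires ggplot2 (suggested dependency); the tidy data behind the
#' figure come from [ce_plane()].
#'
#' @param draws Data frame with `delta_cost`, `delta_qaly` and optionally
#'   `scenario`.
#' @param lambdas Thresholds drawn as rays through the origin, GBP/QALY.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, lambdas = c(20000, 30000)) {
  require_ggplot2()
  aes_args <- if ("scenario" %in% names(draws)) {
    ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                 colour = .data$scenario)
  } else {
    ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)
  }
  p <- ggplot2::ggplot(draws, aes_args) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)")
  for (l in lambdas) {
    p <- p + ggplot2::geom_abline(slope = l, intercept = 0, linetype = "dashed",
                                  linewidth = 0.3)
  }
  p
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param curves Data frame from [ceac()], optionally with a `scenario`
#'   column to draw one curve per scenario.
#' @param markers Thresholds to mark with vertical dotted lines.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curves, markers = c(20000, 30000)) {
  require_ggplot2()
  aes_args <- if ("scenario" %in% names(curves)) {
    ggplot2::aes(x = .data$lambda, y = .data$probability,
                 colour = .data$scenario)
  } else {
    ggplot2::aes(x = .data$lambda, y = .data$probability)
  }
  ggplot2::ggplot(curves, aes_args) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = markers, linetype = "dotted",
                        linewidth = 0.3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective")
}

#' Plot a tornado diagram
#'
#' @param tor A `tornado` data frame from [one_way_tornado()].
#' @param base_icer Base-case ICER drawn as a vertical reference line.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, base_icer = NULL) {
  require_ggplot2()
  tor$parameter <- factor(tor$parameter, levels = rev(tor$parameter))
  p <- ggplot2::ggplot(tor, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = "ICER (GBP per QALY)", y = NULL)
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed")
  }
  p
}

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; install it or use the tidy data directly")
  }
}
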