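#' Tornado diagram
#'
#' Horizontal bars from the ICER at each parameter's low value to the ICER
#' at its high value, widest span on top, with the willingness-to-pay
#' threshold as a vertical reference line. Entries whose ICER is undefined
#' or dominated at an endpoint are dropped from the plot (they carry no
#' finite bar); the returned table from [tornado()] still lists them.
#'
#' @param tornado_tb Output of [tornado()].
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_tb, wtp = 5e6) {
  tb <- tornado_tb[is.finite(tornado_tb$icer_low) &
                     is.finite(tornado_tb$icer_high), ]
  tb$parameter <- factor(tb$parameter, levels = rev(tb$parameter))
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = wtp, colour = "goldenrod", linewidth = 1) +
    ggplot2::labs(x = "ICER (yen/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac_tb Output of [ceac()].
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tb, wtp = 5e6) {
  ggplot2::ggplot(ceac_tb, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                        colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = wtp, colour = "goldenrod") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (yen/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter plot
#'
#' One point per PSA sample on the incremental plane, with the 95%
#' confidence ellipse and the willingness-to-pay line through the origin.
#'
#' @param summary_obj Output of [scatter_summary()].
#' @param wtp Willingness-to-pay threshold (slope of the reference line).
#' @return A ggplot object.
#' @export
plot_ice_scatter <- function(summary_obj, wtp = 5e6) {
  pts <- summary_obj$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, colour = "goldenrod") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental effectiveness (QALY)",
                  y = "Incremental cost (yen)") +
    ggplot2::theme_minimal()
  el <- summary_obj$ellipse
  if (!is.null(el)) {
    theta <- seq(0, 2 * pi, length.out = 181)
    circ <- cbind(el$semi_axes[1] * cos(theta), el$semi_axes[2] * sin(theta))
    path <- sweep(circ %*% t(el$directions), 2, el$center, "+")
    p <- p + ggplot2::geom_path(
      data = data.frame(d_qaly = path[, 1], d_cost = path[, 2]),
      colour = "forestgreen")
  }
  p
}
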