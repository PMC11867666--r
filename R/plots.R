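#' Plot the cost-effectiveness plane
#'
#' Each point is one PSA draw (incremental QALY gain against incremental
#' cost, rapid test minus culture); the dashed line is the
#' willingness-to-pay threshold, below-right of which a draw has positive
#' net monetary benefit. Draws in the south-east quadrant are dominant
#' (cheaper and more effective).
#'
#' @param psa A `psa_results` object.
#' @param wtp Willingness-to-pay slope to draw; defaults to the value the
#'   PSA was run with.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = attr(psa, "wtp")) {
  stopifnot(inherits(psa, "psa_results"))
  ggplot2::ggplot(as.data.frame(psa),
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Incremental QALY gain", y = "Incremental cost (GBP)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A `ceacurve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceacurve"))
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars span the net monetary benefit reached at each
#' parameter's low and high range endpoint, ordered by influence; the
#' vertical line marks the base-case NMB.
#'
#' @param tt A `tornado_table` from [tornado()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(tt) {
  stopifnot(inherits(tt, "tornado_table"))
  df <- as.data.frame(tt)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_low, xend = .data$nmb_high,
                                       yend = .data$parameter),
                          linewidth = 3, colour = "steelblue4", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(tt, "base_nmb"), linetype = "dashed") +
    ggplot2::labs(x = "Net monetary benefit (GBP)", y = NULL,
                  title = "One-way sensitivity of NMB") +
    ggplot2::theme_minimal()
}
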