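# Figure helpers: overestimation scatter and strategy-comparison curves.

#' Scatter of VOP-bounded versus actual SAR
#'
#' One point per probe vector; the unity line marks zero overestimation and
#' a cross marks the vector with the maximum relative overestimation.
#'
#' @param report an `evaluation_report`.
#' @param max_points subsample cap for plotting.
#' @return a ggplot object.
#' @export
plot_overestimation <- function(report, max_points = 20000L) {
  stopifnot(inherits(report, "evaluation_report"))
  idx <- seq_len(report$n_vectors)
  if (length(idx) > max_points)
    idx <- unique(c(round(seq(1L, report$n_vectors, length.out = max_points)),
                    report$argmax_vector_index))
  df <- data.frame(actual = report$actual_sar[idx], vop = report$vop_sar[idx])
  am <- report$argmax_vector_index
  ggplot2::ggplot(df, ggplot2::aes(x = actual, y = vop)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "goldenrod") +
    ggplot2::annotate("point", x = report$actual_sar[am], y = report$vop_sar[am],
                      shape = 4, colour = "red", size = 3) +
    ggplot2::labs(x = "actual max local SAR (W/kg)",
                  y = "VOP-bounded SAR (W/kg)",
                  title = sprintf("%s: %d VOPs, max relative overestimation %.1f %%",
                                  report$strategy_tag, report$n_vops,
                                  report$max_relative_overestimation))
}

#' Maximum relative overestimation versus number of VOPs
#'
#' One curve per strategy (and seed); both axes summarize [comparison_curve()]
#' output. The y axis is logarithmic.
#'
#' @param curves a `comparison_curves` data frame.
#' @return a ggplot object.
#' @export
plot_comparison_curves <- function(curves) {
  stopifnot(inherits(curves, "comparison_curves"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = n_vops,
                               y = max_relative_overestimation,
                               colour = strategy,
                               group = interaction(strategy, seed))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(shape = 4, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of VOPs (pre-VOPs included)",
                  y = "max relative overestimation (%)")
}
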