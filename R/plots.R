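# ggplot2 displays for fitted curves, ring profiles, correlation matrices
# and classifier score distributions.

#' @describeIn fit_4pl Plot the fitted competitive curve over the data
#'   (OD against log10 concentration).
#' @param object An `fq_4pl`.
#' @param ... Unused.
#' @export
autoplot.fq_4pl <- function(object, ...) {
  d <- object$data[object$data$concentration > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration,
                                       y = .data$od)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (ng/mL)", y = "OD (450 nm)")
  if (!object$censored) {
    cf <- object$coefficients
    grid <- tibble(concentration = exp(seq(log(min(d$concentration)),
                                           log(max(d$concentration)),
                                           length.out = 120)))
    grid$od <- fourpl(grid$concentration, cf["a"], cf["d"], cf["c"], cf["b"])
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = cf["c"], linetype = "dashed",
                          colour = "grey40")
  }
  p
}

#' @describeIn ring_betweenness Bar chart of the per-residue ring
#'   betweenness profile (non-zero residues only).
#' @param object An `fq_ring_profile`.
#' @param ... Unused.
#' @export
autoplot.fq_ring_profile <- function(object, ...) {
  d <- object$profile[object$profile$betweenness > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label,
                                                     .data$node_id),
                                  y = .data$betweenness)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "residue", y = "betweenness with ring node",
                  title = paste0("ring betweenness sum = ",
                                 round(object$ring_sum))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @describeIn correlation_matrix Heatmap of the node correlation matrix.
#' @param object An `fq_correlation`.
#' @param ... Unused.
#' @export
autoplot.fq_correlation <- function(object, ...) {
  m <- unclass(object)
  d <- tibble(i = rep(seq_len(nrow(m)), times = ncol(m)),
              j = rep(seq_len(ncol(m)), each = nrow(m)),
              c = as.vector(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "node", y = "node", fill = "C")
}

#' Histogram of ring betweenness scores by class
#'
#' @param data Hapten table with `ring_sum` and `label` columns (e.g.
#'   [reference_betweenness()]).
#' @param bin_width Bin width (default 1000).
#' @param threshold Optional cut-off drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(data, bin_width = 1000, threshold = 4000) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$ring_sum,
                                          fill = .data$label)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            closed = "left", position = "stack",
                            colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(cross_reactive = "seagreen",
                                          non_cross_reactive = "pink")) +
    ggplot2::labs(x = "quinolone-ring betweenness sum", y = "haptens")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed")
  }
  p
}
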