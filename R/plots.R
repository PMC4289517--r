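# Lightweight base-graphics views of the main result objects.

#' Plot a sample-size accuracy curve
#'
#' Median accuracy versus sample size with the 95% bootstrap band, one
#' panel overlay per classifier.
#'
#' @param x a `sample_size_curve` from [accuracy_vs_n()].
#' @param ... passed to [plot()].
#' @export
plot.sample_size_curve <- function(x, ...) {
  cls <- unique(x$classifier)
  cols <- stats::setNames(seq_along(cls) + 1, cls)
  plot(NA, xlim = range(x$size), ylim = range(c(x$ci_lo, x$ci_hi)),
       xlab = "sample size", ylab = "classification accuracy", ...)
  for (cl in cls) {
    d <- x[x$classifier == cl, ]
    graphics::polygon(c(d$size, rev(d$size)), c(d$ci_lo, rev(d$ci_hi)),
                      col = grDevices::adjustcolor(cols[cl], 0.2),
                      border = NA)
    graphics::lines(d$size, d$median, col = cols[cl], lwd = 2)
    graphics::points(d$size, d$median, col = cols[cl], pch = 16)
  }
  graphics::legend("bottomright", legend = cls, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Plot a forward-selection accuracy curve
#'
#' Accuracy versus number of top-ranked features, with the selected
#' inflection point marked.
#'
#' @param x a `selection_curve` from [forward_selection()].
#' @param ... passed to [plot()].
#' @export
plot.selection_curve <- function(x, ...) {
  plot(x$curve$k, x$curve$accuracy, type = "b", pch = 16,
       xlab = "number of features", ylab = "classification accuracy", ...)
  graphics::abline(v = x$k_star, lty = 2)
  graphics::mtext(sprintf("k* = %d", x$k_star), at = x$k_star, side = 3,
                  cex = 0.8)
  invisible(x)
}

#' Correlation heatmap with dendrogram ordering
#'
#' Renders a `correlation_result` with pheatmap when available, otherwise
#' with base [graphics::image()] using the stored leaf orders.
#'
#' @param cr a `correlation_result` from [correlation_cluster()].
#' @param ... passed to the underlying plotting function.
#' @export
plot_correlation_heatmap <- function(cr, ...) {
  r <- cr$r[cr$row_order, cr$col_order, drop = FALSE]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(r, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(-1, 1, length.out = 101), ...)
  } else {
    graphics::image(seq_len(ncol(r)), seq_len(nrow(r)), t(r)[, rev(seq_len(nrow(r)))],
                    zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE, ...)
  }
  invisible(cr)
}
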