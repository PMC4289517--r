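# Pearson correlation analysis with hierarchical-cluster ordering, used for
# metabolite-metabolite correlation heatmaps and for anchoring metabolite
# profiles against a clinical-chemistry panel. Distance is 1 - |r| with
# average linkage (configurable): correlation magnitude, not sign, decides
# co-cluster membership.

#' Pairwise Pearson correlations with dendrogram leaf orders
#'
#' Computes the Pearson correlation matrix of the columns of `x` (against
#' the columns of `y` if given), using pairwise complete observations, and
#' orders rows/columns by average-linkage hierarchical clustering on
#' `1 - |r|`. Zero-variance variables are dropped with a message.
#'
#' @param x subjects x variables matrix (e.g. metabolite features).
#' @param y optional second matrix on the same subjects (e.g. the
#'   clinical-chemistry panel); if omitted the result is the square
#'   variable-variable correlation matrix.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return a `correlation_result`: list with `r` (correlation matrix),
#'   `row_order`, `col_order` (leaf orders), `row_hclust`, `col_hclust`.
#' @export
correlation_cluster <- function(x, y = NULL, linkage = "average") {
  x <- as_subject_matrix(x)
  drop_const <- function(m, what) {
    sds <- apply(m, 2, stats::sd, na.rm = TRUE)
    bad <- which(is.na(sds) | sds == 0)
    if (length(bad)) {
      message("dropping ", length(bad), " zero-variance ", what,
              " variable(s)")
      m <- m[, -bad, drop = FALSE]
    }
    m
  }
  x <- drop_const(x, "x")
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  if (is.null(y)) {
    r <- stats::cor(x, use = "pairwise.complete.obs")
    hc <- stats::hclust(stats::as.dist(1 - abs(r)), method = linkage)
    out <- list(r = r, row_order = hc$order, col_order = hc$order,
                row_hclust = hc, col_hclust = hc)
  } else {
    y <- drop_const(as_subject_matrix(y), "y")
    if (ncol(y) < 2) stop("need at least 2 variables in y", call. = FALSE)
    r <- stats::cor(x, y, use = "pairwise.complete.obs")
    rx <- stats::cor(x, use = "pairwise.complete.obs")
    ry <- stats::cor(y, use = "pairwise.complete.obs")
    hx <- stats::hclust(stats::as.dist(1 - abs(rx)), method = linkage)
    hy <- stats::hclust(stats::as.dist(1 - abs(ry)), method = linkage)
    out <- list(r = r, row_order = hx$order, col_order = hy$order,
                row_hclust = hx, col_hclust = hy)
  }
  class(out) <- "correlation_result"
  out
}

#' Variables with the strongest correlations
#'
#' Picks the `k` variables with the highest absolute off-diagonal
#' correlation, the selection used to display "the twenty metabolites with
#' one or more of the highest correlations".
#'
#' @param cr a square `correlation_result`.
#' @param k number of variables to keep.
#' @return character vector of variable names.
#' @export
top_correlated <- function(cr, k = 20) {
  r <- cr$r
  stopifnot(nrow(r) == ncol(r))
  diag(r) <- NA
  strength <- apply(abs(r), 1, max, na.rm = TRUE)
  names(sort(strength, decreasing = TRUE))[seq_len(min(k, length(strength)))]
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d x %d Pearson coefficients (range %.2f..%.2f)\n",
              nrow(x$r), ncol(x$r), min(x$r, na.rm = TRUE),
              max(x$r, na.rm = TRUE)))
  invisible(x)
}
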