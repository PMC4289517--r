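# Feature-importance rankers used inside the bootstrap consensus protocol:
# (1) rank-based univariate statistic (Mann-Whitney standardized rank-sum
# for two classes, Kruskal-Wallis H otherwise), (2) random-forest impurity
# importance, (3) PLS-DA VIP scores. Each ranker maps a (resampled) data
# set to a full ranking of the candidate features, rank 1 = most important.
#
# The univariate statistics are computed vectorised here (tens of thousands
# of feature x resample evaluations make per-feature htest calls
# impractical); the user-facing screen in univariate_screen() keeps the
# stats::wilcox.test / kruskal.test route, and the two agree (tested).

# standardized rank-sum (2 classes) or Kruskal-Wallis H (k classes),
# columnwise; larger = stronger group separation
rank_score <- function(x, y) {
  y <- droplevels(factor(y))
  n <- nrow(x)
  R <- apply(x, 2, rank)
  if (nlevels(y) == 2) {
    g1 <- y == levels(y)[1]
    n1 <- sum(g1); n2 <- n - n1
    W <- colSums(R[g1, , drop = FALSE])
    abs(W - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  } else {
    H <- rep(0, ncol(x))
    for (lv in levels(y)) {
      g <- y == lv
      H <- H + colSums(R[g, , drop = FALSE])^2 / sum(g)
    }
    12 / (n * (n + 1)) * H - 3 * (n + 1)
  }
}

# deterministic full ranking from importance scores (ties: lexical id)
order_by_score <- function(score, ids) {
  ids[order(-score, ids)]
}

rank_univariate <- function(x, y) {
  order_by_score(rank_score(x, y), colnames(x))
}

rank_random_forest <- function(x, y, ntree = 500) {
  m <- randomForest::randomForest(x, y, ntree = ntree)
  imp <- m$importance[, 1]
  order_by_score(unname(imp), colnames(x))
}

rank_plsda <- function(x, y, ncomp = 2) {
  rownames(x) <- seq_len(nrow(x))  # resampled rows need unique identifiers
  m <- mixOmics::plsda(x, y, ncomp = ncomp)
  v <- mixOmics::vip(m)[, ncomp]   # cumulative VIP over all components
  v[!is.finite(v)] <- 0
  order_by_score(unname(v), colnames(x))
}

# choose the PLS-DA component count once by small k-fold CV accuracy
choose_plsda_ncomp <- function(x, y, ncomp_grid = 2:5, folds = 3,
                               seed = NULL) {
  with_seed(seed, {
    y <- droplevels(factor(y))
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    acc <- vapply(ncomp_grid, function(nc) {
      hits <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        m <- mixOmics::plsda(x[tr, , drop = FALSE], y[tr], ncomp = nc)
        p <- stats::predict(m, x[!tr, , drop = FALSE])
        pred <- p$class$max.dist[, nc]
        mean(pred == as.character(y[!tr]))
      }, numeric(1))
      mean(hits)
    }, numeric(1))
    ncomp_grid[which.max(acc)]
  })
}

# stratified bootstrap indices: resample with replacement within each class,
# preserving class counts, so no class can be absent from a resample
stratified_bootstrap <- function(y) {
  y <- factor(y)
  unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    sample(idx, length(idx), replace = TRUE)
  }), use.names = FALSE)
}

#' Bootstrap feature rankings from one ranker family
#'
#' Draws `B` stratified bootstrap resamples (with replacement, class counts
#' preserved) and fits the requested ranker on each, emitting a full ranking
#' of all features per resample. Stratification makes an absent class
#' impossible by construction.
#'
#' @param x subjects x features matrix (complete, typically autoscaled).
#' @param labels class labels (factor; `NA` rows dropped).
#' @param method `"univariate"`, `"random_forest"` or `"plsda"`.
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed; rankings are deterministic given the seed.
#' @param ntree random-forest trees per fit.
#' @param ncomp PLS-DA components; `NULL` selects 2-5 once by 3-fold CV.
#' @return list of `B` character vectors (feature ids, most important
#'   first), each with attributes `method` and `bootstrap`.
#' @export
bootstrap_rankings <- function(x, labels,
                               method = c("univariate", "random_forest",
                                          "plsda"),
                               B = 100, seed = NULL, ntree = 500,
                               ncomp = 2) {
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  x <- as_subject_matrix(x)
  labels <- factor(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("F%04d", seq_len(ncol(x)))
  if (method == "plsda" && is.null(ncomp))
    ncomp <- choose_plsda_ncomp(x, y, seed = derive_seed(seed, 0))
  with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- stratified_bootstrap(y)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      rk <- switch(method,
        univariate = rank_univariate(xb, yb),
        random_forest = rank_random_forest(xb, yb, ntree = ntree),
        plsda = rank_plsda(xb, yb, ncomp = ncomp))
      attr(rk, "method") <- method
      attr(rk, "bootstrap") <- b
      rk
    })
  })
}
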