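# Empirical sample-size assessment: how classification accuracy and
# feature-ranking consistency behave as the number of subjects grows, the
# resampling design used to conclude how many subjects a population
# metabolomics study needs.

#' Classifier accuracy as a function of sample size
#'
#' For each size `n` in `sizes`, draws `B` stratified bootstrap sample sets
#' of `n` subjects (with replacement, class proportions preserved), trains
#' the classifier on each set and measures accuracy out-of-sample on the
#' subjects never drawn into that set. Reports the median accuracy with a
#' 95% bootstrap-percentile confidence interval per size and classifier.
#' The default grid, 50 to 650 in steps of 50, gives 13 evaluation sizes.
#'
#' @param x subjects x features matrix (complete).
#' @param labels binary class labels (`NA` rows dropped).
#' @param sizes increasing vector of sample sizes.
#' @param classifiers subset of `c("random_forest", "svm")`.
#' @param B bootstrap sample sets per size (default 100).
#' @param seed integer seed.
#' @param ntree random-forest trees.
#' @param cost SVM cost; `NULL` selects once from `c(0.1, 1, 10)` by 3-fold
#'   CV at the largest size (radial kernel, default bandwidth).
#' @return a `sample_size_curve` data.frame: `size`, `classifier`,
#'   `median`, `ci_lo`, `ci_hi`, `B`.
#' @export
accuracy_vs_n <- function(x, labels, sizes = seq(50, 650, by = 50),
                          classifiers = c("random_forest", "svm"),
                          B = 100, seed = NULL, ntree = 500, cost = NULL) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  x <- as_subject_matrix(x)
  labels <- factor(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (is.unsorted(sizes, strictly = TRUE))
    stop("`sizes` must be strictly increasing", call. = FALSE)
  if (max(sizes) > length(y))
    stop(sprintf("largest size (%d) exceeds available samples (%d)",
                 max(sizes), length(y)), call. = FALSE)
  if ("svm" %in% classifiers && is.null(cost))
    cost <- choose_svm_cost(x, y, max(sizes), seed = derive_seed(seed, 99))
  cost <- cost %||% 1

  rows <- list()
  for (cl in classifiers) {
    for (si in seq_along(sizes)) {
      n <- sizes[si]
      accs <- with_seed(derive_seed(seed, si * 131 + match(cl, classifiers)), {
        vapply(seq_len(B), function(b) {
          idx <- stratified_subsample(y, n, replace = TRUE)
          heldout <- setdiff(seq_along(y), unique(idx))
          if (length(unique(y[idx])) < 2 || !length(heldout))
            return(NA_real_)
          m <- train_classifier(x[idx, , drop = FALSE], y[idx], cl,
                                ntree, cost)
          mean(predict_classifier(m, x[heldout, , drop = FALSE]) ==
                 as.character(y[heldout]))
        }, numeric(1))
      })
      q <- stats::quantile(accs, c(0.025, 0.5, 0.975), na.rm = TRUE,
                           names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        size = n, classifier = cl, median = q[2], ci_lo = q[1], ci_hi = q[3],
        B = B, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sample_size_curve", "data.frame")
  out
}

# stratified draw of `n` subjects, class proportions preserved (largest
# remainders rounded so the sizes sum to n)
stratified_subsample <- function(y, n, replace = FALSE) {
  tab <- table(y)
  quota <- as.numeric(tab) / length(y) * n
  take <- floor(quota)
  rem <- n - sum(take)
  if (rem > 0) {
    extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1
  }
  take <- pmax(take, 1)  # both classes represented at every size
  unlist(lapply(seq_along(tab), function(i) {
    idx <- which(y == names(tab)[i])
    sample(idx, min(take[i], if (replace) take[i] else length(idx)),
           replace = replace)
  }), use.names = FALSE)
}

choose_svm_cost <- function(x, y, n, grid = c(0.1, 1, 10), folds = 3,
                            seed = NULL) {
  with_seed(seed, {
    idx <- stratified_subsample(y, n)
    xs <- x[idx, , drop = FALSE]; ys <- droplevels(y[idx])
    fold <- integer(length(ys))
    for (lv in levels(ys)) {
      w <- which(ys == lv)
      fold[w] <- sample(rep_len(seq_len(folds), length(w)))
    }
    acc <- vapply(grid, function(cst) {
      mean(vapply(seq_len(folds), function(f) {
        m <- e1071::svm(xs[fold != f, , drop = FALSE], ys[fold != f],
                        kernel = "radial", cost = cst)
        mean(as.character(stats::predict(m, xs[fold == f, , drop = FALSE])) ==
               as.character(ys[fold == f]))
      }, numeric(1)))
    }, numeric(1))
    grid[which.max(acc)]
  })
}

#' Ranking consistency as a function of sample size
#'
#' At each size `n`, draws a stratified subsample (without replacement),
#' runs the bootstrap consensus ranking protocol (the three ranker families
#' aggregated by Borda count) on it, and reports the Spearman correlation
#' between the subsample's aggregated full ranking and the full-data
#' aggregated ranking. A requested size equal to the full sample size uses
#' the full data itself, so its correlation is exactly 1.
#'
#' @inheritParams accuracy_vs_n
#' @param B bootstrap resamples per ranker family.
#' @param ntree,ncomp ranker parameters (see [bootstrap_rankings()]).
#' @return a `consistency_curve` data.frame: `size`, `spearman`.
#' @export
ranking_consistency_vs_n <- function(x, labels, sizes = seq(50, 650, by = 50),
                                     B = 25, seed = NULL, ntree = 500,
                                     ncomp = 2) {
  x <- as_subject_matrix(x)
  labels <- factor(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (max(sizes) > length(y))
    stop("largest size exceeds available samples", call. = FALSE)

  consensus_of <- function(xs, ys, sd) {
    borda_aggregate(c(
      bootstrap_rankings(xs, ys, "univariate", B = B,
                         seed = derive_seed(sd, 1)),
      bootstrap_rankings(xs, ys, "random_forest", B = B,
                         seed = derive_seed(sd, 2), ntree = ntree),
      bootstrap_rankings(xs, ys, "plsda", B = B,
                         seed = derive_seed(sd, 3), ncomp = ncomp)))
  }
  reference <- consensus_of(x, y, derive_seed(seed, 0))
  ref_rank <- stats::setNames(seq_len(nrow(reference)), reference$feature_id)

  spearman <- vapply(seq_along(sizes), function(si) {
    n <- sizes[si]
    if (n == length(y)) return(1)
    idx <- with_seed(derive_seed(seed, 1000 + si),
                     stratified_subsample(y, n))
    cr <- consensus_of(x[idx, , drop = FALSE], droplevels(y[idx]),
                       derive_seed(seed, 2000 + si))
    sub_rank <- stats::setNames(seq_len(nrow(cr)), cr$feature_id)
    stats::cor(ref_rank[names(sub_rank)], sub_rank, method = "spearman")
  }, numeric(1))
  out <- data.frame(size = sizes, spearman = spearman)
  class(out) <- c("consistency_curve", "data.frame")
  out
}
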