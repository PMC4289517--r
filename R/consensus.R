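# Borda-count consensus aggregation of ranked feature lists, and the
# forward-selection remodeling that locates the optimal feature subset at
# the inflection point of the accuracy-vs-k curve.

#' Borda-count aggregation of ranked lists
#'
#' Each list awards `m - rank` points to every feature (`m` features, rank 1
#' = most important, so the top feature gets `m - 1` points and the last
#' gets 0); points are summed across lists and features are ordered by
#' descending total. Ties are broken by mean rank, then lexically by
#' feature id, and recorded.
#'
#' @param lists list of rankings (character vectors over the same feature
#'   set), e.g. from [bootstrap_rankings()].
#' @return a `consensus_ranking` data.frame: `feature_id`, `score`,
#'   `mean_rank`, ordered by descending score; attribute `ties` records any
#'   tie-broken groups.
#' @export
borda_aggregate <- function(lists) {
  if (!length(lists)) stop("no ranked lists supplied", call. = FALSE)
  universe <- sort(lists[[1]])
  m <- length(universe)
  score <- stats::setNames(numeric(m), universe)
  ranksum <- stats::setNames(numeric(m), universe)
  for (l in lists) {
    if (length(l) != m || !identical(sort(as.character(l)), universe))
      stop("all lists must rank the same feature set", call. = FALSE)
    r <- stats::setNames(seq_len(m), as.character(l))
    score <- score + (m - r[universe])
    ranksum <- ranksum + r[universe]
  }
  mean_rank <- ranksum / length(lists)
  ord <- order(-score, mean_rank, universe)
  out <- data.frame(feature_id = universe[ord], score = score[ord],
                    mean_rank = mean_rank[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  tied <- unname(out$feature_id[duplicated(out$score) |
                                  duplicated(out$score, fromLast = TRUE)])
  attr(out, "ties") <- tied
  class(out) <- c("consensus_ranking", "data.frame")
  out
}

# classifier wrappers used by forward selection / sample-size study
train_classifier <- function(x, y, classifier, ntree = 500, cost = 1) {
  if (classifier == "random_forest")
    randomForest::randomForest(x, y, ntree = ntree)
  else
    e1071::svm(x, y, kernel = "radial", cost = cost)
}

predict_classifier <- function(model, x) {
  as.character(stats::predict(model, x))
}

# bootstrap 0.632 accuracy of a classifier on a fixed feature set; the
# resample index sets are supplied so that successive k share them (common
# random numbers keep the accuracy-vs-k curve smooth)
boot632_accuracy <- function(x, y, resamples, classifier, ntree, cost) {
  oob_acc <- vapply(resamples, function(idx) {
    oob <- setdiff(seq_along(y), unique(idx))
    if (!length(oob)) return(NA_real_)
    m <- train_classifier(x[idx, , drop = FALSE], y[idx], classifier,
                          ntree, cost)
    mean(predict_classifier(m, x[oob, , drop = FALSE]) ==
           as.character(y[oob]))
  }, numeric(1))
  m_full <- train_classifier(x, y, classifier, ntree, cost)
  resub <- mean(predict_classifier(m_full, x) == as.character(y))
  list(accuracy = 0.368 * resub + 0.632 * mean(oob_acc, na.rm = TRUE),
       oob = oob_acc)
}

# inflection rule: smallest k (with a full trailing window) at which the
# moving-average accuracy gain per added feature drops below `min_gain`
find_inflection <- function(accuracy, window = 5, min_gain = 0.0025) {
  k_max <- length(accuracy)
  if (k_max == 1) return(1L)
  gains <- diff(accuracy)
  first_k <- window + 1
  if (k_max >= first_k) {
    for (k in first_k:k_max) {
      if (mean(gains[(k - window):(k - 1)]) < min_gain) return(as.integer(k))
    }
  }
  as.integer(k_max)
}

#' Forward-selection remodeling along a consensus ranking
#'
#' Starting from the most important feature and adding the next one at a
#' time, trains a classifier on the top-k features and estimates its
#' accuracy by bootstrap out-of-sample evaluation (0.632 estimator over
#' `eval_resamples` stratified resamples, shared across k). The optimal
#' subset size `k*` is the inflection point of the accuracy-vs-k curve:
#' the smallest k at which the window-5 moving-average gain per added
#' feature falls below 0.25 percentage points, capped at `k_max`.
#'
#' @param ranking a `consensus_ranking` (or character vector of feature ids
#'   in rank order).
#' @param x subjects x features matrix.
#' @param labels class labels.
#' @param classifier `"random_forest"` (default) or `"svm"`.
#' @param k_max largest subset size evaluated.
#' @param eval_resamples bootstrap resamples per k.
#' @param seed integer seed.
#' @param ntree,cost classifier hyper-parameters.
#' @param window,min_gain inflection-detection parameters.
#' @return a `selection_curve`: list with `curve` (data.frame `k`,
#'   `accuracy`, `accuracy_sd`), `k_star`, `accuracy_at_k_star`,
#'   `features` (the top-`k_star` ids).
#' @export
forward_selection <- function(ranking, x, labels,
                              classifier = c("random_forest", "svm"),
                              k_max = 30, eval_resamples = 20, seed = NULL,
                              ntree = 500, cost = 1, window = 5,
                              min_gain = 0.0025) {
  classifier <- match.arg(classifier)
  ids <- if (is.data.frame(ranking)) ranking$feature_id else as.character(ranking)
  x <- as_subject_matrix(x)
  labels <- factor(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (nlevels(y) < 2) stop("labels must contain at least 2 classes",
                           call. = FALSE)
  if (k_max > length(ids))
    stop("k_max exceeds the number of ranked features", call. = FALSE)
  with_seed(seed, {
    resamples <- lapply(seq_len(eval_resamples),
                        function(b) stratified_bootstrap(y))
    acc <- numeric(k_max); acc_sd <- numeric(k_max)
    for (k in seq_len(k_max)) {
      res <- boot632_accuracy(x[, ids[seq_len(k)], drop = FALSE], y,
                              resamples, classifier, ntree, cost)
      acc[k] <- res$accuracy
      acc_sd[k] <- stats::sd(res$oob, na.rm = TRUE)
    }
    k_star <- find_inflection(acc, window = window, min_gain = min_gain)
    structure(list(curve = data.frame(k = seq_len(k_max), accuracy = acc,
                                      accuracy_sd = acc_sd),
                   k_star = k_star,
                   accuracy_at_k_star = acc[k_star],
                   features = ids[seq_len(k_star)]),
              class = "selection_curve")
  })
}

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf("<selection_curve> k = 1..%d, k* = %d (accuracy %.3f)\n",
              nrow(x$curve), x$k_star, x$accuracy_at_k_star))
  invisible(x)
}

#' Consensus feature selection for one clinical hypothesis
#'
#' The full protocol: three ranker families (univariate rank statistic,
#' random-forest importance, PLS-DA VIP) x `B` stratified bootstrap
#' resamples each, Borda-count aggregation of the 3B rankings, then
#' forward-selection remodeling to the inflection point. Also reports the
#' classifier accuracy on the selected subset against the full feature set
#' (selection should not cost accuracy).
#'
#' @inheritParams forward_selection
#' @param B bootstrap resamples per ranker family (default 100).
#' @param ncomp PLS-DA components (see [bootstrap_rankings()]).
#' @return list with `ranking` (`consensus_ranking`), `selection`
#'   (`selection_curve`), `selected` (feature ids), `accuracy_selected`,
#'   `accuracy_full`.
#' @export
consensus_select <- function(x, labels, B = 100,
                             classifier = c("random_forest", "svm"),
                             k_max = 30, eval_resamples = 20, seed = NULL,
                             ntree = 500, cost = 1, ncomp = 2) {
  classifier <- match.arg(classifier)
  lists <- c(
    bootstrap_rankings(x, labels, "univariate", B = B,
                       seed = derive_seed(seed, 1)),
    bootstrap_rankings(x, labels, "random_forest", B = B,
                       seed = derive_seed(seed, 2), ntree = ntree),
    bootstrap_rankings(x, labels, "plsda", B = B,
                       seed = derive_seed(seed, 3), ncomp = ncomp))
  ranking <- borda_aggregate(lists)
  sel <- forward_selection(ranking, x, labels, classifier = classifier,
                           k_max = k_max, eval_resamples = eval_resamples,
                           seed = derive_seed(seed, 4), ntree = ntree,
                           cost = cost)
  # with/without-selection comparison on a common evaluation
  xm <- as_subject_matrix(x)
  labels <- factor(labels)
  keep <- !is.na(labels)
  xm <- xm[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  cmp <- with_seed(derive_seed(seed, 5), {
    resamples <- lapply(seq_len(eval_resamples),
                        function(b) stratified_bootstrap(y))
    c(sel = boot632_accuracy(xm[, sel$features, drop = FALSE], y, resamples,
                             classifier, ntree, cost)$accuracy,
      full = boot632_accuracy(xm, y, resamples, classifier, ntree,
                              cost)$accuracy)
  })
  list(ranking = ranking, selection = sel, selected = sel$features,
       accuracy_selected = unname(cmp["sel"]),
       accuracy_full = unname(cmp["full"]))
}
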