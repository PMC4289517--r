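# Imputation and scaling applied to the filtered subjects x features matrix
# before statistical analysis: missing cells are replaced by the feature
# mean over observed subjects (features are only eligible if at most 20% of
# their values are missing), then every feature is autoscaled (mean-centred
# and normalized to unit variance).

as_subject_matrix <- function(x) {
  if (inherits(x, "integrated_matrix")) x$data else as.matrix(x)
}

#' Mean-impute missing values per feature
#'
#' @param x subjects x features numeric matrix (or `integrated_matrix`).
#' @param max_missing maximum tolerated per-feature missing fraction
#'   (default 0.2); features above it should have been removed by the
#'   presence filter, and hitting one here is an error directing the caller
#'   back to the filters.
#' @return matrix with every missing cell replaced by the feature's mean
#'   over observed subjects.
#' @export
impute_missing <- function(x, max_missing = 0.2) {
  x <- as_subject_matrix(x)
  miss <- colMeans(is.na(x))
  if (any(miss >= 1))
    stop("feature(s) entirely missing: ",
         paste(utils::head(colnames(x)[miss >= 1], 3), collapse = ", "),
         call. = FALSE)
  over <- miss > max_missing
  if (any(over))
    stop(sprintf(
      "%d feature(s) exceed %.0f%% missing values (e.g. %s); apply the presence/QA filters first",
      sum(over), 100 * max_missing,
      paste(utils::head(colnames(x)[over], 3), collapse = ", ")),
      call. = FALSE)
  for (j in which(miss > 0)) {
    mj <- is.na(x[, j])
    x[mj, j] <- mean(x[!mj, j])
  }
  x
}

#' Autoscale a matrix (unit variance, mean centred)
#'
#' @param x subjects x features numeric matrix with no missing values.
#' @return matrix where every feature has mean 0 and sample SD 1.
#' @export
autoscale <- function(x) {
  x <- as_subject_matrix(x)
  if (anyNA(x))
    stop("autoscale requires a complete matrix; impute first", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(x)[sds == 0], 3), collapse = ", "),
         call. = FALSE)
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Rank-based univariate screen
#'
#' For each feature, compares the group distributions with the Mann-Whitney
#' U test (2 groups; exact p for small samples without ties, normal
#' approximation with tie correction otherwise, `stats::wilcox.test`
#' defaults) or the Kruskal-Wallis test (more than 2 groups). No
#' multiple-testing correction is applied by default; set `adjust = "BH"`
#' for Benjamini-Hochberg adjusted p-values in an extra column.
#'
#' @param x subjects x features matrix (complete).
#' @param labels factor of group labels (length `nrow(x)`; `NA` rows are
#'   dropped).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `feature_id`, `statistic` (U or H), `p`
#'   (and `p_adj` when requested).
#' @export
univariate_screen <- function(x, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- as_subject_matrix(x)
  labels <- factor(labels)
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  k <- nlevels(labels)
  if (k < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (any(table(labels) < 2))
    warning("a group has fewer than 2 members; p-values will be unstable",
            call. = FALSE)
  res <- vapply(seq_len(ncol(x)), function(j) {
    if (k == 2) {
      ht <- suppressWarnings(
        stats::wilcox.test(x[labels == levels(labels)[1], j],
                           x[labels == levels(labels)[2], j]))
    } else {
      ht <- stats::kruskal.test(x[, j], labels)
    }
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  out <- data.frame(feature_id = colnames(x) %||%
                      sprintf("F%04d", seq_len(ncol(x))),
                    statistic = res[1, ], p = res[2, ],
                    stringsAsFactors = FALSE)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Fits `values ~ A * B` by least squares and reports main-effect and
#' interaction F statistics, degrees of freedom and p-values. Type II sums
#' of squares are used, the standard choice for unbalanced observational
#' designs without strong interactions; on balanced data they coincide with
#' sequential sums of squares. Rows where `values` or a factor is `NA` are
#' dropped, so the residual df reflect the complete cases (the usual
#' F(1, 901)-style reporting).
#'
#' @param values numeric response (one feature).
#' @param factorA,factorB factors (>= 2 levels each after dropping `NA`).
#' @return an `anova_result` data.frame: `term`, `df`, `df_res`, `F`, `p`.
#' @export
two_way_anova <- function(values, factorA, factorB) {
  keep <- !(is.na(values) | is.na(factorA) | is.na(factorB))
  d <- data.frame(y = values[keep], A = droplevels(factor(factorA[keep])),
                  B = droplevels(factor(factorB[keep])))
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2)
    stop("both factors need at least 2 levels", call. = FALSE)
  if (any(table(d$A, d$B) == 0))
    stop("empty factor cell: the interaction model is not estimable",
         call. = FALSE)
  fit <- stats::lm(y ~ A * B, data = d)
  aov2 <- car::Anova(fit, type = 2)
  terms <- c("A", "B", "A:B")
  df_res <- aov2[["Df"]][rownames(aov2) == "Residuals"]
  idx <- match(terms, rownames(aov2))
  out <- data.frame(
    term = c("factorA", "factorB", "interaction"),
    df = aov2[["Df"]][idx], df_res = df_res,
    F = aov2[["F value"]][idx], p = aov2[["Pr(>F)"]][idx],
    stringsAsFactors = FALSE)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise level comparisons of `factor` with studentized-range
#' adjusted p-values. Supplying `covariate` collapses over a second factor
#' the way a two-way model does ("independent of gender"): the comparison
#' uses the residual variance of `values ~ covariate + factor`.
#'
#' @param values numeric response.
#' @param factor_ factor whose levels are compared.
#' @param covariate optional second factor adjusted for.
#' @return data.frame `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, factor_, covariate = NULL) {
  keep <- !(is.na(values) | is.na(factor_))
  if (!is.null(covariate)) keep <- keep & !is.na(covariate)
  f <- droplevels(factor(factor_[keep]))
  if (nlevels(f) < 2) stop("need at least 2 factor levels", call. = FALSE)
  if (any(table(f) == 0)) stop("factor level with 0 observations",
                               call. = FALSE)
  d <- data.frame(y = values[keep], f = f)
  if (is.null(covariate)) {
    fit <- stats::aov(y ~ f, data = d)
  } else {
    d$g <- droplevels(factor(covariate[keep]))
    fit <- stats::aov(y ~ g + f, data = d)
  }
  tk <- stats::TukeyHSD(fit, which = "f")$f
  out <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
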