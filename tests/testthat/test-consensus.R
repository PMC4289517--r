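test_that("the vectorised ranking statistic agrees with wilcox.test / kruskal.test", {
  withr::local_seed(71)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y2 <- factor(rep(c("a", "b"), each = 30))
  sc <- metabodrift:::rank_score(x, y2)
  # |standardized W| must order features exactly as |U - n1*n2/2|
  u <- apply(x, 2, function(v)
    abs(unname(wilcox.test(v[y2 == "a"], v[y2 == "b"])$statistic) - 450))
  expect_equal(order(-sc), order(-u))
  y3 <- factor(rep(c("a", "b", "c"), each = 20))
  sc3 <- metabodrift:::rank_score(x, y3)
  h <- apply(x, 2, function(v) unname(kruskal.test(v, y3)$statistic))
  expect_equal(unname(sc3), unname(h), tolerance = 1e-10)
})

test_that("Borda aggregation reproduces the worked three-list example", {
  lists <- list(c("A", "B", "C"), c("B", "A", "C"), c("A", "C", "B"))
  cr <- borda_aggregate(lists)
  expect_equal(cr$feature_id, c("A", "B", "C"))
  expect_equal(cr$score, c(5, 3, 1))
})

test_that("Borda aggregation: identity, permutation invariance, repeated lists", {
  single <- list(c("x", "q", "m", "a"))
  expect_equal(borda_aggregate(single)$feature_id, single[[1]])
  withr::local_seed(72)
  lists <- replicate(7, sample(letters[1:6]), simplify = FALSE)
  cr1 <- borda_aggregate(lists)
  cr2 <- borda_aggregate(rev(lists))
  expect_identical(cr1, cr2)
  # L copies of one list return that list's order for any L
  for (L in c(1, 3, 10))
    expect_equal(borda_aggregate(rep(single, L))$feature_id, single[[1]])
  expect_error(borda_aggregate(list(c("a", "b"), c("a", "c"))),
               "same feature set")
})

test_that("Borda equals an independent brute-force rank-sum on random instances", {
  withr::local_seed(73)
  for (i in 1:200) {
    m <- sample(2:6, 1); L <- sample(1:5, 1)
    ids <- replicate(m, paste(sample(letters, 3), collapse = ""))
    while (anyDuplicated(ids)) ids <- make.unique(ids)
    lists <- replicate(L, sample(ids), simplify = FALSE)
    cr <- borda_aggregate(lists)
    # oracle: loop-and-count points independently
    pts <- setNames(numeric(m), ids)
    for (l in lists) for (r in seq_len(m)) pts[l[r]] <- pts[l[r]] + (m - r)
    expect_equal(cr$score[match(ids, cr$feature_id)], unname(pts[ids]))
    # ordering consistent with scores
    expect_true(all(diff(cr$score) <= 0))
  }
})

test_that("bootstrap rankings: count, determinism, and planted-effect recovery", {
  dat <- make_labelled_matrix(n = 60, p = 40, n_informative = 1, effect = 3,
                              seed = 74)
  for (mth in c("univariate", "random_forest", "plsda")) {
    B <- 20
    lists <- bootstrap_rankings(dat$x, dat$y, mth, B = B, seed = 75,
                                ntree = 100)
    expect_length(lists, B)
    lists2 <- bootstrap_rankings(dat$x, dat$y, mth, B = B, seed = 75,
                                 ntree = 100)
    expect_identical(lists, lists2)
    # a 3-SD feature among pure noise is ranked first almost always
    top1 <- vapply(lists, `[`, "", 1)
    expect_gte(mean(top1 == dat$informative), 0.95)
  }
  expect_error(bootstrap_rankings(dat$x, factor(rep("a", 60)), "univariate"),
               "2 classes")
})

test_that("forward selection: degenerate range, k* detection, null labels", {
  dat <- make_labelled_matrix(n = 80, p = 15, n_informative = 3, effect = 2,
                              seed = 76)
  ranking <- borda_aggregate(
    bootstrap_rankings(dat$x, dat$y, "univariate", B = 10, seed = 77))
  sc1 <- forward_selection(ranking, dat$x, dat$y, k_max = 1,
                           eval_resamples = 5, seed = 78, ntree = 60)
  expect_equal(nrow(sc1$curve), 1)
  expect_equal(sc1$k_star, 1L)
  # permuted labels: accuracy stays inside the binomial null band at each k
  withr::local_seed(79)
  ynull <- sample(dat$y)
  scn <- forward_selection(ranking, dat$x, ynull, k_max = 6,
                           eval_resamples = 10, seed = 80, ntree = 60)
  p0 <- max(table(ynull)) / length(ynull)
  band <- 3 * sqrt(p0 * (1 - p0) / length(ynull))
  expect_true(all(abs(scn$curve$accuracy - p0) < band + 0.1))
  expect_error(forward_selection(ranking, dat$x, dat$y, k_max = 99),
               "k_max")
})

test_that("the inflection rule picks the plateau of a synthetic accuracy curve", {
  acc <- c(0.55, 0.65, 0.72, 0.78, 0.82, 0.85, 0.87, 0.88, 0.885,
           rep(0.886, 11))
  k <- metabodrift:::find_inflection(acc, window = 5, min_gain = 0.0025)
  expect_true(k >= 10 && k <= 14)
  expect_equal(metabodrift:::find_inflection(rep(0.9, 3)), 3L)
  expect_equal(metabodrift:::find_inflection(0.7), 1L)
})

test_that("consensus_select is deterministic and beats no-selection on planted data", {
  dat <- make_labelled_matrix(n = 70, p = 25, n_informative = 4, effect = 1.5,
                              seed = 81)
  res <- consensus_select(dat$x, dat$y, B = 8, k_max = 10,
                          eval_resamples = 8, seed = 82, ntree = 80)
  res2 <- consensus_select(dat$x, dat$y, B = 8, k_max = 10,
                           eval_resamples = 8, seed = 82, ntree = 80)
  expect_identical(res$selected, res2$selected)
  expect_identical(res$ranking$score, res2$ranking$score)
  # most planted features surface near the top of the consensus ranking
  expect_gte(length(intersect(res$ranking$feature_id[1:6], dat$informative)),
             3)
  # selection does not cost accuracy relative to the full feature set
  expect_gte(res$accuracy_selected, res$accuracy_full - 0.05)
})

test_that("consensus ranking is invariant to feature column order", {
  dat <- make_labelled_matrix(n = 50, p = 12, n_informative = 2, effect = 2,
                              seed = 83)
  r1 <- borda_aggregate(bootstrap_rankings(dat$x, dat$y, "univariate",
                                           B = 15, seed = 84))
  perm <- sample(ncol(dat$x))
  r2 <- borda_aggregate(bootstrap_rankings(dat$x[, perm], dat$y,
                                           "univariate", B = 15, seed = 84))
  expect_identical(r1$feature_id, r2$feature_id)
  expect_identical(r1$score, r2$score)
})
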