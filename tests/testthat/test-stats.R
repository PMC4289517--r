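test_that("mean imputation fills gaps and enforces the 20% missingness cap", {
  x <- cbind(F1 = c(1, NA, 3), F2 = c(2, 2, 2))
  expect_equal(impute_missing(x, max_missing = 0.4),
               cbind(F1 = c(1, 2, 3), F2 = c(2, 2, 2)))
  expect_identical(impute_missing(cbind(a = 1:3 * 1.0)), cbind(a = 1:3 * 1.0))
  x21 <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  x21[1:21, 2] <- NA   # 21% missing
  expect_error(impute_missing(x21), "filters")
  x_all <- cbind(a = rep(NA_real_, 5))
  expect_error(impute_missing(x_all), "entirely missing")
})

test_that("autoscaling gives unit-variance zero-mean features and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- autoscale(x)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_equal(unname(autoscale(z)), unname(z), tolerance = 1e-12)
  expect_error(autoscale(cbind(a = rep(4, 3))), "zero-variance")
  expect_error(autoscale(cbind(a = c(1, NA, 3))), "impute")
})

test_that("Mann-Whitney screen matches exhaustive permutation on a small split", {
  x <- cbind(f = c(1, 2, 3, 4))
  lab <- factor(c("g1", "g1", "g2", "g2"))
  res <- univariate_screen(x, lab)
  expect_equal(res$statistic, 0)   # U = 0 for fully separated {1,2} vs {3,4}
  # exhaustive two-sided p over all 6 labelings: 2/6
  expect_equal(res$p, 1 / 3)
  # perfectly interleaved groups (no separation) -> p = 1
  res2 <- univariate_screen(cbind(f = c(1, 4, 2, 3)),
                            factor(c("a", "a", "b", "b")))
  expect_equal(res2$p, 1)
})

test_that("Kruskal-Wallis screen equals the direct rank-sum formula", {
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  lab <- factor(rep(c("a", "b", "c"), each = 2))
  res <- univariate_screen(x, lab)
  # brute-force H on ranks 1..6: group rank sums 3, 7, 11
  n <- 6
  H <- 12 / (n * (n + 1)) * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 3 * (n + 1)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$p, kruskal.test(x[, 1], lab)$p.value)
})

test_that("screen p-values are invariant under monotone transforms", {
  withr::local_seed(31)
  x <- matrix(rlnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("f", 1:5)))
  lab <- factor(rep(c("a", "b"), 40))
  p_raw <- univariate_screen(x, lab)$p
  p_log <- univariate_screen(log(x), lab)$p
  p_cube <- univariate_screen(x^3, lab)$p
  expect_equal(p_raw, p_log)
  expect_equal(p_raw, p_cube)
})

test_that("null p-values are uniform across 2000 simulated features", {
  withr::local_seed(32)
  # group sizes large enough that the normal-approximation p-values are
  # nearly continuous (the exact small-sample p is lattice-valued, which a
  # KS test against U(0,1) would flag for discreteness alone)
  x <- matrix(rnorm(120 * 2000), 120, 2000,
              dimnames = list(NULL, sprintf("f%04d", 1:2000)))
  lab <- factor(rep(c("a", "b"), each = 60))
  p <- univariate_screen(x, lab)$p
  # residual ties among the approximated p-values only trigger ks.test's
  # cosmetic warning; the statistic itself is what matters here
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("two-way ANOVA matches a hand-worked SS decomposition on balanced 2x2", {
  # 3 observations per cell
  d <- expand.grid(rep_ = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- c(4, 5, 6,   8, 9, 10,   5, 6, 7,   12, 13, 14)
  res <- two_way_anova(d$y, d$A, d$B)
  # oracle: explicit sums of squares (balanced, so unambiguous)
  gm <- mean(d$y)
  ssA <- 6 * sum((tapply(d$y, d$A, mean) - gm)^2)
  ssB <- 6 * sum((tapply(d$y, d$B, mean) - gm)^2)
  cell <- tapply(d$y, list(d$A, d$B), mean)
  ssCells <- 3 * sum((cell - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((d$y - ave(d$y, d$A, d$B))^2)
  dfE <- 12 - 4
  f_oracle <- c(ssA / 1, ssB / 1, ssAB / 1) / (ssE / dfE)
  expect_equal(res$F, f_oracle, tolerance = 1e-8)
  expect_equal(res$df, c(1, 1, 1))
  expect_equal(res$df_res, rep(dfE, 3))
  expect_equal(res$p, pf(f_oracle, 1, dfE, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("balanced data: Type II SS equal sequential SS", {
  withr::local_seed(41)
  d <- expand.grid(rep_ = 1:5, A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) + 0.5 * as.numeric(d$B)
  res <- two_way_anova(d$y, d$A, d$B)
  seq_tab <- anova(lm(y ~ A * B, d))
  expect_equal(res$F, seq_tab$`F value`[1:3], tolerance = 1e-10)
})

test_that("ANOVA null case, unbalanced df bookkeeping and error paths", {
  # all cell means equal -> F ~ 0 (up to noise-free arithmetic), p ~ 1
  d <- expand.grid(rep_ = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- rep(5, 12) + rep(c(-0.01, 0, 0.01), 4)
  res <- two_way_anova(d$y, d$A, d$B)
  expect_true(all(res$F < 1e-10))
  expect_true(all(res$p > 0.999))
  # unbalanced: residual df = n - ab
  withr::local_seed(42)
  n <- 37
  A <- factor(sample(c("m", "f"), n, TRUE))
  B <- factor(sample(c("x", "y", "z"), n, TRUE))
  y <- rnorm(n)
  res2 <- two_way_anova(y, A, B)
  expect_equal(unique(res2$df_res), n - 6)
  expect_error(two_way_anova(y, factor(rep("m", n)), B), "2 levels")
  A_empty <- factor(ifelse(B == "x", "m", "f"))  # empty (f, x) cell
  expect_error(two_way_anova(y, A_empty, B), "empty factor cell")
})

# independent oracle: studentized-range upper tail by double numeric
# integration (outer over the chi distribution of the pooled SD)
ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    g <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * s))^(k - 1)
    k * integrate(g, -8, 8, rel.tol = 1e-10)$value
  }
  dens_s <- function(s) 2 * (df / 2)^(df / 2) / gamma(df / 2) *
    s^(df - 1) * exp(-df * s^2 / 2)
  cdf <- integrate(function(s) vapply(s, function(si)
    dens_s(si) * inner(si), numeric(1)), 0, 5, rel.tol = 1e-9)$value
  1 - cdf
}

test_that("Tukey HSD matches the k=2 t-test identity and a numeric-integration oracle", {
  withr::local_seed(51)
  # k = 2: Tukey adjusted p equals the pooled-variance t-test p
  y <- rnorm(20) + rep(c(0, 0.8), each = 10)
  f <- factor(rep(c("a", "b"), each = 10))
  tk <- tukey_hsd(y, f)
  tt <- t.test(y ~ f, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)
  # k = 3: adjusted p equals the independently integrated tail probability
  y3 <- rnorm(18) + rep(c(0, 0.5, 1.2), each = 6)
  f3 <- factor(rep(c("a", "b", "c"), each = 6))
  tk3 <- tukey_hsd(y3, f3)
  fit <- aov(y3 ~ f3)
  mse <- deviance(fit) / df.residual(fit)
  means <- tapply(y3, f3, mean)
  pairs <- combn(levels(f3), 2)
  for (i in seq_len(ncol(pairs))) {
    qi <- abs(means[pairs[2, i]] - means[pairs[1, i]]) / sqrt(mse / 6)
    oracle <- ptukey_oracle(qi, k = 3, df = df.residual(fit))
    row <- tk3[tk3$contrast == paste(pairs[2, i], pairs[1, i], sep = "-"), ]
    expect_equal(row$p_adj, oracle, tolerance = 1e-6)
  }
})

test_that("Tukey null case, covariate adjustment, and dominance over the raw t-test", {
  withr::local_seed(52)
  # equal-mean groups: adjusted p near 1
  y <- rnorm(30)
  f <- factor(rep(c("a", "b"), 15))
  expect_gt(tukey_hsd(y, f)$p_adj, 0.05)
  # adjusted p >= unadjusted pairwise t-test p for every pair (k = 3)
  y3 <- rnorm(30) + rep(c(0, 0.4, 0.9), each = 10)
  f3 <- factor(rep(c("a", "b", "c"), each = 10))
  tk <- tukey_hsd(y3, f3)
  for (i in seq_len(nrow(tk))) {
    lv <- strsplit(tk$contrast[i], "-")[[1]]
    sub <- f3 %in% lv
    praw <- t.test(y3[sub] ~ droplevels(f3[sub]), var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[i], praw - 1e-10)
  }
  # collapsing over a second factor changes the residual df
  g <- factor(rep(c("m", "f"), 15))
  tk_adj <- tukey_hsd(y3, f3, covariate = g)
  expect_s3_class(tk_adj, "data.frame")
  expect_error(tukey_hsd(y3, factor(rep("a", 30))), "2 factor levels")
})

test_that("correlation clustering keeps correlated blocks contiguous", {
  withr::local_seed(61)
  n <- 120
  base1 <- rnorm(n); base2 <- rnorm(n)
  x <- cbind(sapply(1:4, function(i) base1 + rnorm(n, 0, 0.4)),
             sapply(1:4, function(i) base2 + rnorm(n, 0, 0.4)))
  colnames(x) <- c(paste0("u", 1:4), paste0("v", 1:4))
  cr <- correlation_cluster(x)
  expect_equal(unname(diag(cr$r)), rep(1, 8))
  expect_true(all(cr$r >= -1 & cr$r <= 1))
  blocks <- substr(colnames(x)[cr$row_order], 1, 1)
  expect_equal(length(rle(blocks)$lengths), 2)  # each block contiguous
  # y = -x gives r = -1
  cr2 <- correlation_cluster(cbind(a = 1:10, b = -(1:10) * 2))
  expect_equal(cr2$r["a", "b"], -1)
  # zero-variance variables are dropped with a message
  expect_message(correlation_cluster(cbind(x, const = rep(1, n))),
                 "zero-variance")
})

test_that("feature-vs-clinical correlation uses both dendrograms; top-k picks the hubs", {
  withr::local_seed(62)
  n <- 80
  clin <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("CHOL", "TRIG", "GLUC")))
  feat <- cbind(m1 = clin[, "CHOL"] + rnorm(n, 0, 0.3),
                m2 = rnorm(n), m3 = rnorm(n))
  cr <- correlation_cluster(feat, clin)
  expect_equal(dim(cr$r), c(3, 3))
  expect_gt(cr$r["m1", "CHOL"], 0.8)
  sq <- correlation_cluster(cbind(feat, clin))
  expect_true(all(c("m1", "CHOL") %in% top_correlated(sq, 2)))
})
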