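test_that("permutation test degenerate and extreme cases", {
  A <- matrix(1, 4, 3)
  B <- matrix(1, 4, 3)
  res <- permutation_test(A, B, n_perm = 200, seed = 1)
  expect_equal(res$stat, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # groups separated by ~100 SDs: among C(30,15) partitions only the true
  # split reaches the observed gap, so the add-one minimum is attained
  set.seed(2)
  A <- matrix(rnorm(30, 0, 1), 15, 2)
  B <- matrix(rnorm(30, 200, 1), 15, 2)
  res <- permutation_test(A, B, n_perm = 10000, seed = 3)
  expect_equal(res$p, rep(1 / 10001, 2))
  res_raw <- permutation_test(A, B, n_perm = 1000, seed = 3, plus_one = FALSE)
  expect_equal(res_raw$p, rep(0, 2))
  expect_error(permutation_test(A[1, , drop = FALSE], B), "2 subjects")
})

test_that("Monte-Carlo p-values agree with the exhaustive 3-vs-3 oracle", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(3); b <- rnorm(3, 1)
    exact <- oracle_exact_perm_p(a, b)
    res <- permutation_test(matrix(a), matrix(b), n_perm = 4000, seed = i)
    # binomial error around the exact proportion (plus-one correction shifts
    # the estimate by at most 1/(n_perm+1))
    tol <- 4 * sqrt(exact * (1 - exact) / 4000) + 2 / 4001
    expect_lt(abs(res$p - exact), tol)
  }
})

test_that("permutation p-values are invariant to group relabeling", {
  set.seed(12)
  A <- matrix(rnorm(5 * 4), 5, 4)
  B <- matrix(rnorm(7 * 4, 0.5), 7, 4)
  r1 <- permutation_test(A, B, n_perm = 500, seed = 9)
  r2 <- permutation_test(B, A, n_perm = 500, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$stat, r2$stat)
})

test_that("permutation test is reproducible given a seed", {
  set.seed(13)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12, 0.3), 4, 3)
  expect_identical(permutation_test(A, B, 300, seed = 7)$p,
                   permutation_test(A, B, 300, seed = 7)$p)
})

test_that("BH adjustment matches hand-computed and oracle values", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(0.07, 5)), rep(0.07, 5))
  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(fdr_bh(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(fdr_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("q-values dominate p-values and flag at the threshold", {
  set.seed(22)
  p <- runif(40)^2
  res <- permutation_test(matrix(rnorm(40), 4, 10),
                          matrix(rnorm(40), 4, 10), 200, seed = 5)
  expect_true(all(res$q >= res$p))
  expect_identical(res$significant, res$q < 0.05)
})

test_that("logistic AUC equals the midrank Mann-Whitney statistic", {
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
    d <- tibble::tibble(
      feature = c(rnorm(n0), rnorm(n1, runif(1, -1, 1))),
      label = rep(c("ctl", "case"), c(n0, n1))
    )
    rep_ <- logistic_auc(d, feature, label, positive = "case")
    # the classifier ranks subjects by fitted probability; its trapezoidal
    # AUC must equal U/(n1*n0) computed on those scores
    expect_equal(rep_$auc,
                 oracle_auc_mw(fitted(rep_$fit), d$label == "case"),
                 tolerance = 1e-12)
    expect_true(rep_$ci_low <= rep_$auc && rep_$auc <= rep_$ci_high)
    expect_gte(rep_$ci_low, 0); expect_lte(rep_$ci_high, 1)
  }
})

test_that("AUC endpoints: perfect separation and uninformative features", {
  d <- tibble::tibble(x = c(1:6, 11:16), g = rep(c("a", "b"), each = 6))
  rep_ <- logistic_auc(d, x, g, positive = "b")
  expect_identical(rep_$auc, 1)
  expect_true(rep_$separation)
  d0 <- tibble::tibble(x = rep(2.5, 12), g = rep(c("a", "b"), each = 6))
  expect_identical(logistic_auc(d0, x, g, positive = "b")$auc, 0.5)
  d1 <- tibble::tibble(x = rnorm(6), g = rep("a", 6))
  expect_error(logistic_auc(d1, x, g), "two classes")
})

test_that("AUC is invariant under strictly monotone feature transforms", {
  # for an informative feature the classifier's ranking is rank-based, so
  # increasing transforms leave the AUC unchanged (for an uninformative
  # feature the in-sample orientation itself is not identifiable)
  set.seed(32)
  for (i in 1:10) {
    d <- tibble::tibble(x = c(rnorm(12), rnorm(12, 1.5)),
                        g = rep(c("a", "b"), each = 12))
    a1 <- logistic_auc(d, x, g, positive = "b")$auc
    d$x <- exp(3 * d$x) + 2
    a2 <- logistic_auc(d, x, g, positive = "b")$auc
    expect_equal(a1, a2, tolerance = 1e-9)
    d$x <- -d$x  # amplitude reversal flips the fitted slope, not the AUC
    expect_equal(logistic_auc(d, x, g, positive = "b")$auc, a2,
                 tolerance = 1e-9)
  }
})

test_that("glance/tidy/roc_points expose the classification report", {
  d <- tibble::tibble(x = c(rnorm(8), rnorm(8, 2)),
                      g = rep(c("a", "b"), each = 8))
  rep_ <- logistic_auc(d, x, g, positive = "b")
  gl <- glance(rep_)
  expect_identical(names(gl), c("auc", "ci_low", "ci_high", "separation"))
  td <- tidy(rep_)
  expect_identical(td$term, c("(Intercept)", "x"))
  expect_true(all(diff(rep_$roc_points$fpr) >= 0))
  expect_true(all(diff(rep_$roc_points$tpr) >= 0))
})

test_that("ANCOVA matches a normal-equations oracle", {
  set.seed(41)
  n <- 10
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = n / 2),
    z = rnorm(n),
    y = 0.5 + 0.8 * rnorm(n)
  )
  d$y <- d$y + 1.2 * d$z + ifelse(d$g == "b", 0.9, 0)
  rep_ <- ancova_oneway(d, y, g, z)
  # explicit least squares: full model vs covariate-only model
  X1 <- cbind(1, d$z, as.integer(d$g == "b"))
  X0 <- cbind(1, d$z)
  rss <- function(X, y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rss1 <- rss(X1, d$y); rss0 <- rss(X0, d$y)
  F_oracle <- (rss0 - rss1) / (rss1 / (n - 3))
  p_oracle <- stats::pf(F_oracle, 1, n - 3, lower.tail = FALSE)
  expect_equal(rep_$F, F_oracle, tolerance = 1e-8)
  expect_equal(rep_$p, p_oracle, tolerance = 1e-8)
  expect_equal(unname(rep_$df), c(1, n - 3))
  expect_equal(rep_$eta_sq, (rss0 - rss1) / rss0, tolerance = 1e-8)
})

test_that("ANCOVA edge cases: no group effect, bounds, collinearity", {
  set.seed(42)
  n <- 12
  g <- rep(c("a", "b"), each = n / 2)
  z <- rnorm(n)
  # outcome built orthogonal to the group contrast given the covariate
  e <- residuals(lm(rnorm(n) ~ z + factor(g)))
  d <- tibble::tibble(g = g, z = z, y = 2 * z + e)
  expect_lt(ancova_oneway(d, y, g, z)$F, 1e-16)
  for (i in 1:20) {
    d2 <- tibble::tibble(g = g, z = rnorm(n), y = rnorm(n))
    es <- ancova_oneway(d2, y, g, z)$eta_sq
    expect_gte(es, 0); expect_lte(es, 1)
  }
  d3 <- tibble::tibble(g = g, z = as.integer(g == "b"), y = rnorm(n))
  expect_error(ancova_oneway(d3, y, g, z), "collinear")
  expect_error(ancova_oneway(d3[c(1, 2, 7, 8), ], y, g, z), "3 subjects")
})
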