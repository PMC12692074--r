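test_that("group descriptives and t-tests behave at the edges", {
  set.seed(3)
  x <- rnorm(30, 50, 5)
  df <- data.frame(group = rep(c("normal", "albp"), each = 30L),
                   SBA = c(x, x))
  s <- describe_groups(df)
  expect_equal(s$normal_mean, s$albp_mean)
  expect_equal(s$p_value, 1, tolerance = 1e-9)
  expect_error(describe_groups(data.frame(group = c("a", "b"), v = 1:2)),
               "fewer than 2")
  # zero variance in both groups flags an undefined t
  dz <- data.frame(group = rep(c("a", "b"), each = 3L), v = rep(1, 6L))
  expect_true(is.na(describe_groups(dz)$p_value))
  # Student vs Welch are both available
  df2 <- data.frame(group = rep(c("a", "b"), c(10L, 40L)),
                    v = c(rnorm(10, 0, 1), rnorm(40, 1, 4)))
  expect_false(identical(describe_groups(df2)$p_value,
                         describe_groups(df2, var_equal = FALSE)$p_value))
})

test_that("Spearman matrix equals brute-force rank correlation", {
  set.seed(8)
  df <- data.frame(a = rnorm(10), b = rnorm(10), c = sample(1:4, 10, TRUE))
  sm <- spearman_matrix(df, c("a", "b", "c"))
  for (p in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    brute <- cor(rank(df[[p[1L]]]), rank(df[[p[2L]]]))
    expect_equal(sm$rho[p[1L], p[2L]], brute, tolerance = 1e-12)
  }
  expect_equal(sm$rho, t(sm$rho))
  # monotone pairs hit +/-1 with p ~ 0
  dm <- data.frame(x = 1:8, y = exp(1:8), z = -(1:8)^3)
  sm2 <- spearman_matrix(dm, c("x", "y", "z"))
  expect_equal(sm2$rho["x", "y"], 1)
  expect_equal(sm2$rho["x", "z"], -1)
  expect_lt(sm2$p["x", "y"], 1e-9)
  expect_warning(spearman_matrix(data.frame(a = rep(1, 5), b = 1:5),
                                 c("a", "b")),
                 "constant")
})

test_that("Cohen's d matches the published effect sizes from the printed
          summaries", {
  expect_lt(abs(cohens_d(39.4, 7.2, 50, 44.5, 9.2, 50)$d - 0.617), 1e-3)
  expect_lt(abs(cohens_d(65.4, 9.4, 50, 70.0, 10.1, 50)$d - 0.471), 1e-3)
  expect_equal(cohens_d(10, 2, 20, 10, 3, 20)$d, 0)
  # invariant under common affine rescaling
  d1 <- cohens_d(39.4, 7.2, 50, 44.5, 9.2, 50)$d
  d2 <- cohens_d(39.4 * 2 + 5, 7.2 * 2, 50, 44.5 * 2 + 5, 9.2 * 2, 50)$d
  expect_equal(d1, d2)
  expect_error(cohens_d(1, 0, 10, 1, 0, 10), "pooled")
})

test_that("noncentral-t sample size is minimal and monotone", {
  expect_identical(required_sample_size(0.471), 72L)
  # brute-force minimality over the full scan range
  pw <- vapply(2:200, function(n) {
    df <- 2 * n - 2
    tc <- qt(0.975, df)
    pt(tc, df, 0.471 * sqrt(n / 2), lower.tail = FALSE) +
      pt(-tc, df, 0.471 * sqrt(n / 2))
  }, numeric(1L))
  expect_identical(min(which(pw >= 0.80)) + 1L, 72L)
  # monotone in effect size, with small n at large d
  n1 <- required_sample_size(1)
  n2 <- required_sample_size(2)
  expect_lte(n2, 7L)
  expect_lt(n2, n1)
  expect_lt(n1, required_sample_size(0.5))
  expect_error(required_sample_size(0), "nonzero")
  expect_error(required_sample_size(1e-6, n_max = 1e4L), "exceeds")
})

test_that("empirical ROC equals the exhaustive pair-count U statistic and
          the Youden/K-S identity holds", {
  set.seed(13)
  for (i in 1:60) {
    n0 <- sample(2:30, 1L); n1 <- sample(2:30, 1L)
    x0 <- sample(1:12, n0, TRUE) + rnorm(n0, 0, 0.01 * (i %% 2))
    x1 <- sample(3:14, n1, TRUE) + rnorm(n1, 0, 0.01 * (i %% 2))
    r <- roc_analysis(x0, x1)
    expect_equal(r$auc, pair_count_auc(x0, x1), tolerance = 1e-12)
    expect_equal(r$youden_j, directional_ks(x0, x1), tolerance = 1e-12)
    expect_equal(r$youden_j, r$ks_metric)
  }
})

test_that("ROC handles separation, ties and the largest-cutoff tie rule", {
  r <- roc_analysis(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  r2 <- roc_analysis(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$auc, 7 / 9)          # 6 wins + 2 ties of 9 pairs
  expect_equal(r2$optimal_cutoff, 4)   # J ties at 2, 3, 4 -> largest wins
  expect_error(roc_analysis(numeric(0), 1:3), "non-empty")
})

test_that("ROC orientation is fixed: reversed separation reports AUC below
          one half", {
  r <- roc_analysis(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$auc, 0)
  set.seed(4)
  r2 <- roc_analysis(rnorm(500, 5), rnorm(500, 4))
  expect_lt(r2$auc, 0.5)
})

test_that("AUC is invariant under strictly increasing transforms and is one
          half for identical distributions", {
  set.seed(21)
  x0 <- rgamma(200, 2); x1 <- rgamma(300, 3)
  expect_equal(roc_analysis(x0, x1)$auc,
               roc_analysis(log(x0), log(x1))$auc, tolerance = 1e-12)
  expect_equal(roc_analysis(x0, x0)$auc, 0.5, tolerance = 1e-12)
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  x0 <- rnorm(80, 39.4, 7.2); x1 <- rnorm(80, 44.5, 9.2)
  r <- roc_analysis(x0, x1)
  ref <- pROC::roc(response = rep(c(0, 1), each = 80L),
                   predictor = c(x0, x1), direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("normality screen flags skewed data but passes Gaussian data", {
  set.seed(6)
  df <- data.frame(g = rnorm(200), s = rexp(200))
  nf <- normality_flags(df, c("g", "s"))
  expect_false(nf$nonnormal[nf$variable == "g"])
  expect_true(nf$nonnormal[nf$variable == "s"])
})
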