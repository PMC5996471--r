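test_that("normality screens separate normal from skewed and bimodal samples", {
  set.seed(101)
  gauss <- rnorm(500)
  res <- normality_tests(gauss)
  expect_gt(res$ks_p, 0.05)
  expect_gt(res$shapiro_p, 0.05)

  expo <- rexp(500)
  res_e <- normality_tests(expo)
  expect_lt(res_e$ks_p, 0.01)
  expect_lt(res_e$shapiro_p, 0.01)

  bimodal <- c(rnorm(250, -4), rnorm(250, 4))
  expect_lt(normality_tests(bimodal)$shapiro_p, 0.01)

  expect_error(normality_tests(rep(1, 10)), "constant")
})

test_that("Mann-Whitney U, z and p follow the rank-sum conventions", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_statistic, 0)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z_value, 0)
  expect_equal(same$p_value, 1)

  # tied example: exact permutation p over all 70 assignments
  p_enum <- mw_enum_p(c(1, 2, 3, 4), c(2, 3, 4, 5))
  got <- mann_whitney(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(got$p_value, p_enum, tolerance = 1e-12)

  # large-sample path agrees with wilcox.test's normal approximation
  set.seed(3)
  a <- rnorm(80); b <- rnorm(90, 0.4)
  got2 <- mann_whitney(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got2$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got2$u_statistic, unname(ref$statistic))
})

test_that("exact small-sample p matches exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:60) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:min(8, 10 - n1), 1)
    a <- round(rnorm(n1), sample(c(0, 3), 1))  # sometimes forces ties
    b <- round(rnorm(n2), 3)
    got <- mann_whitney(a, b)
    expect_equal(got$p_value, mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("ROC handles orientation, perfect separation and the null", {
  # chaotic features fall in disease: positives score lower
  roc <- roc_curve(c(1, 1.2, 1.4, 2, 2.2, 2.4),
                   c("e", "e", "e", "n", "n", "n"), positive = "e",
                   orientation = "lower")
  expect_equal(roc$auc, 1.0)

  set.seed(9)
  null_roc <- roc_curve(rnorm(1000), rep(c("e", "n"), 500), positive = "e")
  expect_gt(null_roc$auc, 0.45)
  expect_lt(null_roc$auc, 0.55)

  expect_error(roc_curve(1:5, rep("e", 5), positive = "e"), "both classes")
})

test_that("AUC equals U/(n1 n2) and matches pROC on every tested dataset", {
  set.seed(23)
  for (rep in 1:30) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    scores <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n2), 1))  # with ties
    labels <- c(rep("e", n1), rep("n", n2))
    roc <- roc_curve(scores, labels, positive = "e", orientation = "lower")
    # U counts pairs where a negative exceeds a positive (midrank ties)
    u <- mann_whitney(scores[labels == "n"],
                      scores[labels == "e"])$u_statistic
    expect_equal(roc$auc, u / (n1 * n2), tolerance = 1e-9)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(31)
    scores <- rnorm(200)
    labels <- rep(c("e", "n"), 100)
    roc <- roc_curve(scores, labels, positive = "e", orientation = "lower")
    ref <- pROC::roc(labels, scores, levels = c("n", "e"),
                     direction = ">", quiet = TRUE)
    expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-9)
  }
})

test_that("cut-off metrics are computed by direct counting", {
  s <- c(1, 1, 1, 2, 2, 2)
  l <- c("e", "e", "e", "n", "n", "n")
  cm <- cutoff_metrics(s, l, threshold = 1.5, positive = "e")
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  cm_lo <- cutoff_metrics(s, l, threshold = 0.5, positive = "e")
  expect_equal(cm_lo$sensitivity, 0)
  expect_equal(cm_lo$specificity, 1)

  set.seed(5)
  scores <- rnorm(100)
  labels <- sample(c("e", "n"), 100, replace = TRUE)
  thr <- median(scores)
  got <- cutoff_metrics(scores, labels, thr, positive = "e")
  expect_equal(got$sensitivity,
               sum(scores < thr & labels == "e") / sum(labels == "e"))
  expect_equal(got$specificity,
               sum(scores >= thr & labels == "n") / sum(labels == "n"))
})

test_that("group comparison reports medians, IQRs and the U test", {
  set.seed(11)
  v <- c(rnorm(50, 2), rnorm(50, 1))
  g <- rep(c("normal", "encephalopathy"), each = 50)
  cmp <- compare_groups(v, g, "cd")
  expect_equal(cmp$groups[[which(cmp$group_names == "normal")]]$median,
               median(v[g == "normal"]))
  expect_lt(cmp$p_value, 0.001)

  roc <- roc_curve(v, g, positive = "encephalopathy", orientation = "lower")
  op <- best_cutoff(roc, "sensitivity", 0.8)
  expect_gte(op$sensitivity, 0.8)
})
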