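#' Normality screening (Kolmogorov-Smirnov and Shapiro-Wilk)
#'
#' Both tests against a normal distribution, the K-S test with mean and SD
#' estimated from the data (which makes its p-value conservative in the
#' Lilliefors sense; it is used here only as a screen before choosing a
#' nonparametric group test). Shapiro-Wilk is limited to 5000 values; a
#' deterministic thinning is applied above that.
#'
#' @param values Numeric vector (>= 3 values, non-constant).
#' @return A list with `ks_p` and `shapiro_p`.
#' @export
normality_tests <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values")
  if (sd(values) == 0) stop("constant input: normality tests undefined")
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), sd(values)))
  sw_in <- if (length(values) > 5000)
    values[round(seq(1, length(values), length.out = 5000))] else values
  sw <- stats::shapiro.test(sw_in)
  list(ks_p = unname(ks$p.value), shapiro_p = unname(sw$p.value))
}

#' Mann-Whitney U test with z approximation
#'
#' Rank-sum test for a location difference between two samples. U is
#' computed from midranks for the first sample (`U = R1 - n1(n1+1)/2`, so
#' complete separation with `a` below `b` gives U = 0). The z value uses
#' the normal approximation with tie-corrected variance and a 0.5
#' continuity correction. The two-sided p-value
#' `P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)` is exact when the sample is
#' small: from the null U distribution (base `pwilcox`) without ties up to
#' `n1 + n2 = 50`, or by full permutation enumeration with ties up to
#' `n1 + n2 = 12`; otherwise the normal approximation is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A list of class `mann_whitney`: `u_statistic` (for sample a),
#'   `z_value`, `p_value`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$u_statistic  # 0
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((nt + 1) - tie_term / (nt * (nt - 1)))
  z <- if (sigma2 > 0)
    (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2) else 0
  has_ties <- any(tie_tab > 1)
  d <- abs(u1 - mu)
  if (!has_ties && nt <= 50) {
    # two-sided tail of the exact (symmetric) null U distribution
    p <- min(1, pwilcox(floor(mu - d + 1e-9), n1, n2) +
               1 - pwilcox(ceiling(mu + d - 1e-9) - 1, n1, n2))
    method <- "exact"
  } else if (has_ties && nt <= 12) {
    # tied data: enumerate U over all group assignments of the midranks
    us <- apply(utils::combn(nt, n1), 2,
                function(s) sum(r[s])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= d - 1e-9)
    method <- "exact (permutation)"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  structure(list(u_statistic = u1, z_value = z, p_value = p,
                 method = method, n1 = n1, n2 = n2),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), z = %.3f, p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$z_value, x$p_value, x$method))
  invisible(x)
}

#' Nonparametric comparison of a feature between two groups
#'
#' Medians and interquartile ranges per group plus the Mann-Whitney U test
#' ([mann_whitney()]), the summary used to contrast a chaotic feature
#' between normal and encephalopathy-like epochs.
#'
#' @param values Numeric feature values.
#' @param groups Factor or character vector of group membership (exactly
#'   two levels).
#' @param feature_name Label carried into the result.
#' @return A list of class `group_comparison` with per-group `n`,
#'   `median`, `iqr_lo`, `iqr_hi` and the test's `u_statistic`, `z_value`,
#'   `p_value`.
#' @export
compare_groups <- function(values, groups, feature_name = "feature") {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  mw <- mann_whitney(g1, g2)
  qs <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(v), median = q[2], iqr_lo = q[1], iqr_hi = q[3])
  }
  structure(list(feature_name = feature_name, group_names = levels(groups),
                 groups = list(qs(g1), qs(g2)),
                 u_statistic = mw$u_statistic, z_value = mw$z_value,
                 p_value = mw$p_value, method = mw$method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s\n", x$feature_name))
  for (i in 1:2) {
    g <- x$groups[[i]]
    cat(sprintf("  %-16s n = %4d  median %.4f  IQR %.4f-%.4f\n",
                x$group_names[i], g$n, g$median, g$iqr_lo, g$iqr_hi))
  }
  cat(sprintf("  Mann-Whitney U = %g, z = %.3f, p = %.4g\n",
              x$u_statistic, x$z_value, x$p_value))
  invisible(x)
}

#' ROC analysis of a score against binary labels
#'
#' Sweeps every distinct score as a threshold. With orientation
#' `"lower"` (the default here, because the chaotic features decrease in
#' disease) a case is called positive when its score is strictly below the
#' threshold; `"higher"` calls positives above. Sensitivity and
#' specificity are reported per threshold and the AUC is computed by the
#' trapezoid rule, which with midrank tie handling equals the Mann-Whitney
#' statistic U/(n1*n2) under the matched orientation.
#'
#' @param scores Numeric scores.
#' @param labels Vector of class labels.
#' @param positive The label counted as positive (diseased).
#' @param orientation `"lower"` or `"higher"`: which direction of score
#'   indicates the positive class.
#' @return A list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `orientation`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive,
                      orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s <- as.numeric(scores)
  thr <- sort(unique(s))
  thr <- c(thr, Inf)
  if (orientation == "lower") {
    sens <- vapply(thr, function(t) mean(s[pos] < t), numeric(1))
    spec <- vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))
  } else {
    sens <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(s[!pos] < t), numeric(1))
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  x <- c(0, fpr[ord], 1); y <- c(0, sens[ord], 1)
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, orientation = orientation,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s-score-indicates-positive): AUC = %.4f (%d pos, %d neg)\n",
              x$orientation, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity and specificity at a single cut-off
#'
#' Direct counting at a requested threshold: with orientation `"lower"`,
#' sensitivity is the fraction of positives scoring strictly below the
#' threshold and specificity the fraction of negatives scoring at or above
#' it (mirrored for `"higher"`).
#'
#' @inheritParams roc_curve
#' @param threshold The cut-off to evaluate.
#' @return A list with `sensitivity` and `specificity`.
#' @export
cutoff_metrics <- function(scores, labels, threshold, positive,
                           orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  pos <- labels == positive
  s <- as.numeric(scores)
  if (orientation == "lower")
    list(sensitivity = mean(s[pos] < threshold),
         specificity = mean(s[!pos] >= threshold))
  else
    list(sensitivity = mean(s[pos] >= threshold),
         specificity = mean(s[!pos] < threshold))
}

#' Operating point achieving a requested sensitivity or specificity
#'
#' Scans the ROC thresholds for those whose `target` metric is at least
#' `level` and returns the one with the best complementary metric, the
#' cut-off-reporting style used when proposing diagnostic thresholds.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @param target `"sensitivity"` or `"specificity"`.
#' @param level Required minimum for the target metric.
#' @return A list with `threshold`, `sensitivity`, `specificity`.
#' @export
best_cutoff <- function(roc, target = c("sensitivity", "specificity"),
                        level = 0.8) {
  target <- match.arg(target)
  primary <- roc[[target]]
  other <- if (target == "sensitivity") roc$specificity else roc$sensitivity
  ok <- which(primary >= level)
  if (length(ok) == 0) stop("no threshold reaches the requested level")
  best <- ok[which.max(other[ok])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best])
}
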