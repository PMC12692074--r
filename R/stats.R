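# Group-comparison statistics: descriptives with t-tests, Spearman
# correlation matrices, Cohen's d, noncentral-t sample size, and empirical
# ROC analysis with Youden / Kolmogorov-Smirnov cutoff selection.

#' Per-group descriptive summary with two-sample t-tests
#'
#' Mean, SD, max, min and n per variable and group, plus an independent
#' two-sided t-test per variable (pooled-variance Student by default, Welch
#' optional).  Variables with zero variance in both groups get `p = NA` and
#' are flagged.
#'
#' @param data data.frame containing a group column and numeric variables.
#' @param variables variables to summarize; default all numeric columns.
#' @param group_col name of the grouping column (exactly two groups).
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return object of class `group_summary`: a data.frame with one row per
#'   variable and columns `<group>_mean/sd/max/min/n` and `p_value`.
#' @export
describe_groups <- function(data, variables = NULL, group_col = "group",
                            var_equal = TRUE) {
  stopifnot(group_col %in% names(data))
  groups <- unique(data[[group_col]])
  if (length(groups) != 2L)
    stop("describe_groups needs exactly two groups, got ",
         length(groups), call. = FALSE)
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1L)) &
                               names(data) != group_col]
  rows <- lapply(variables, function(v) {
    x0 <- data[[v]][data[[group_col]] == groups[1L]]
    x1 <- data[[v]][data[[group_col]] == groups[2L]]
    x0 <- x0[is.finite(x0)]; x1 <- x1[is.finite(x1)]
    if (length(x0) < 2L || length(x1) < 2L)
      stop("variable ", v, " has fewer than 2 observations in a group",
           call. = FALSE)
    p <- if (stats::sd(x0) == 0 && stats::sd(x1) == 0) NA_real_
    else stats::t.test(x1, x0, var.equal = var_equal)$p.value
    out <- data.frame(variable = v,
                      g1_mean = mean(x0), g1_sd = stats::sd(x0),
                      g1_max = max(x0), g1_min = min(x0), g1_n = length(x0),
                      g2_mean = mean(x1), g2_sd = stats::sd(x1),
                      g2_max = max(x1), g2_min = min(x1), g2_n = length(x1),
                      p_value = p, stringsAsFactors = FALSE)
    names(out) <- sub("^g1", groups[1L], names(out))
    names(out) <- sub("^g2", groups[2L], names(out))
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- as.character(groups)
  attr(out, "test") <- if (var_equal) "student" else "welch"
  class(out) <- c("group_summary", "data.frame")
  out
}

#' @export
print.group_summary <- function(x, digits = 3L, ...) {
  cat("Two-group summary (", attr(x, "test"), " t-test): ",
      paste(attr(x, "groups"), collapse = " vs "), "\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation matrix
#'
#' Symmetric matrix of tie-corrected Spearman rho with p-values from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param data data.frame of observations.
#' @param variables columns to correlate (>= 2); complete cases are used
#'   pairwise across all listed variables.
#' @return list of class `spearman_matrix` with `rho` and `p` matrices and
#'   `n`.
#' @export
spearman_matrix <- function(data, variables) {
  stopifnot(length(variables) >= 2L, all(variables %in% names(data)))
  m <- as.matrix(data[, variables, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  const <- apply(m, 2L, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant column(s), rho undefined: ",
            paste(variables[const], collapse = ", "), call. = FALSE)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA_real_
  structure(list(rho = rho, p = p, n = n), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 3L, ...) {
  cat("Spearman rank correlations (n =", x$n, ")\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Normality screen
#'
#' Shapiro-Wilk and Kolmogorov-Smirnov (against the fitted normal) p-values
#' per variable, as a reporting flag for whether rank-based correlation is
#' preferable; never used to switch methods automatically.
#'
#' @param data data.frame.
#' @param variables numeric columns to screen.
#' @param alpha flag threshold.
#' @return data.frame with `shapiro_p`, `ks_p` and logical `nonnormal`.
#' @export
normality_flags <- function(data, variables, alpha = 0.05) {
  rows <- lapply(variables, function(v) {
    x <- data[[v]]; x <- x[is.finite(x)]
    sw <- tryCatch(stats::shapiro.test(x)$p.value,
                   error = function(e) NA_real_)
    ks <- tryCatch(suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value),
      error = function(e) NA_real_)
    data.frame(variable = v, shapiro_p = sw, ks_p = ks,
               nonnormal = isTRUE(sw < alpha) || isTRUE(ks < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohen's d standardized mean difference
#'
#' `d = (m1 - m0) / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n0-1) s0^2 + (n1-1) s1^2) / (n0 + n1 - 2))`.
#'
#' @param m0,s0,n0 mean, SD and size of the reference group.
#' @param m1,s1,n1 mean, SD and size of the comparison group.
#' @return object of class `effect_size` with `d` and `pooled_sd`.
#' @examples
#' cohens_d(39.4, 7.2, 50, 44.5, 9.2, 50)  # d = 0.617
#' @export
cohens_d <- function(m0, s0, n0, m1, s1, n1) {
  stopifnot(n0 >= 2, n1 >= 2, s0 >= 0, s1 >= 0)
  sp <- sqrt(((n0 - 1) * s0^2 + (n1 - 1) * s1^2) / (n0 + n1 - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  structure(list(d = (m1 - m0) / sp, pooled_sd = sp), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (pooled SD = %.3f)\n", x$d, x$pooled_sd))
  invisible(x)
}

two_sample_t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- abs(d) * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Required per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group whose two-sided two-sample t-test power,
#' computed from the noncentral t distribution with `df = 2n - 2` and
#' noncentrality `d * sqrt(n / 2)`, reaches the target.
#'
#' @param d standardized mean difference (Cohen's d, nonzero).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param n_max search cap.
#' @return integer n per group.
#' @examples
#' required_sample_size(0.471)  # 72 per group
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 n_max = 1e6L) {
  if (!is.finite(d) || d == 0)
    stop("effect size must be nonzero", call. = FALSE)
  hi <- 2L
  while (two_sample_t_power(hi, d, alpha) < power) {
    hi <- hi * 2L
    if (hi > n_max)
      stop("effect size too small: required n exceeds ", n_max, call. = FALSE)
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {  # power is nondecreasing in n over this range
    mid <- (lo + hi) %/% 2L
    if (two_sample_t_power(mid, d, alpha) >= power) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Empirical ROC analysis with Youden / K-S cutoff selection
#'
#' Builds the empirical ROC at every distinct observed threshold under the
#' fixed orientation "value >= cutoff predicts ALBP" (never auto-flipped, so
#' an AUC below 0.5 is reported as such).  The AUC is the trapezoidal area,
#' which equals the Mann-Whitney U statistic divided by `n0 * n1` with
#' half-credit for ties.  The optimal cutoff maximizes Youden's
#' J = sensitivity + specificity - 1; among tied maxima the largest cutoff
#' value is returned.  Under this orientation J coincides with the
#' directional two-sample K-S statistic `max(F_normal - F_albp)`, reported
#' as `ks_metric`.
#'
#' @param scores_normal scores of the reference (normal) group.
#' @param scores_albp scores of the case (ALBP) group.
#' @return object of class `roc_result` with elements `curve` (data.frame of
#'   `cutoff`, `sensitivity`, `specificity`), `auc`, `optimal_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `youden_j`, `ks_metric`, `n0`, `n1`.
#' @export
roc_analysis <- function(scores_normal, scores_albp) {
  x0 <- scores_normal[is.finite(scores_normal)]
  x1 <- scores_albp[is.finite(scores_albp)]
  if (!length(x0) || !length(x1))
    stop("both score samples must be non-empty", call. = FALSE)
  cuts <- sort(unique(c(x0, x1)), decreasing = TRUE)
  s0 <- sort(x0); s1 <- sort(x1)
  # count of sample values >= each cutoff (left-open interval count gives
  # the number strictly below the cutoff)
  fpr <- (length(x0) - findInterval(cuts, s0, left.open = TRUE)) / length(x0)
  tpr <- (length(x1) - findInterval(cuts, s1, left.open = TRUE)) / length(x1)
  curve <- data.frame(cutoff = cuts, sensitivity = tpr,
                      specificity = 1 - fpr)
  # trapezoid over ((0,0), descending cutoffs ..., (1,1))
  fx <- c(0, fpr); fy <- c(0, tpr)
  if (fx[length(fx)] < 1 || fy[length(fy)] < 1) { fx <- c(fx, 1); fy <- c(fy, 1) }
  auc <- sum(diff(fx) * (utils::head(fy, -1L) + utils::tail(fy, -1L)) / 2)
  j <- curve$sensitivity + curve$specificity - 1
  jmax <- max(j)
  best <- which(j >= jmax - 1e-12)
  pick <- best[which.max(curve$cutoff[best])]
  structure(
    list(curve = curve, auc = auc,
         optimal_cutoff = curve$cutoff[pick],
         sens_at_cutoff = curve$sensitivity[pick],
         spec_at_cutoff = curve$specificity[pick],
         youden_j = jmax, ks_metric = jmax,
         n0 = length(x0), n1 = length(x1)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC (n0 = %d normal, n1 = %d ALBP)\n", x$n0, x$n1))
  cat(sprintf("  AUC = %.3f (orientation: value >= cutoff predicts ALBP)\n",
              x$auc))
  cat(sprintf("  optimal cutoff %.1f: sensitivity %.2f, specificity %.2f\n",
              x$optimal_cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  cat(sprintf("  Youden J = K-S metric = %.3f\n", x$youden_j))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  i <- which(x$curve$cutoff == x$optimal_cutoff)
  graphics::points(1 - x$curve$specificity[i], x$curve$sensitivity[i],
                   pch = 19, col = "firebrick")
  invisible(x)
}

#' Closed-form binormal AUC
#'
#' `Phi((m1 - m0) / sqrt(s0^2 + s1^2))`, the population AUC when both score
#' distributions are Gaussian; analytic cross-check for Monte-Carlo ROC
#' estimates.
#'
#' @param m0,s0 mean and SD of the reference group.
#' @param m1,s1 mean and SD of the case group.
#' @return AUC in (0, 1).
#' @export
binormal_auc <- function(m0, s0, m1, s1) {
  stats::pnorm((m1 - m0) / sqrt(s0^2 + s1^2))
}
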