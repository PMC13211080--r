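#' Paired difference test with normality gating
#'
#' Tests whether two repeated measurements of the same units differ on
#' average. The differences are first checked for normality with the
#' Shapiro-Wilk test; if normal (p >= `alpha`), a paired t-test is used,
#' otherwise the Wilcoxon signed-rank test. Zero-variance differences are a
#' degenerate case reported with p = 1.
#'
#' @param first,second Aligned numeric vectors (>= 3 pairs).
#' @param alpha Significance level of the Shapiro-Wilk gate (default 0.05).
#' @return List with `p_value`, `test` (`"paired_t"`, `"wilcoxon"` or
#'   `"degenerate"`), `mean_diff`, `sd_diff`, `shapiro_p`, `n`.
#' @export
paired_difference_test <- function(first, second, alpha = 0.05) {
  stopifnot(length(first) == length(second), length(first) >= 3,
            !anyNA(first), !anyNA(second))
  d <- first - second
  if (stats::sd(d) == 0) {
    return(list(p_value = 1, test = "degenerate", mean_diff = mean(d),
                sd_diff = 0, shapiro_p = NA_real_, n = length(d)))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw >= alpha) {
    p <- stats::t.test(first, second, paired = TRUE)$p.value
    test <- "paired_t"
  } else {
    p <- stats::wilcox.test(first, second, paired = TRUE, exact = FALSE)$p.value
    test <- "wilcoxon"
  }
  list(p_value = p, test = test, mean_diff = mean(d), sd_diff = stats::sd(d),
       shapiro_p = sw, n = length(d))
}

#' Bland-Altman analysis
#'
#' Bias (mean difference) and 95% limits of agreement,
#' `bias +/- 1.96 * SD(differences)`, between two measurements of the same
#' units. The fixed 1.96 multiplier (not a t quantile) is the conventional
#' large-sample definition of the limits.
#'
#' @param first,second Aligned numeric vectors (>= 3 pairs).
#' @return List of class `bland_altman`: `bias`, `sd_diff`, `lower`,
#'   `upper`, `n`, plus `means` and `diffs` for plotting.
#' @examples
#' bland_altman(c(10, 11, 12), c(11, 11, 11))
#' @export
bland_altman <- function(first, second) {
  stopifnot(length(first) == length(second), length(first) >= 3,
            !anyNA(first), !anyNA(second))
  d <- first - second
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 lower = bias - 1.96 * s, upper = bias + 1.96 * s,
                 n = length(d), means = (first + second) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f +/- %.3f, 95%% limits [%.3f, %.3f], n = %d\n",
              x$bias, x$sd_diff, x$lower, x$upper, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient, two-way random, absolute agreement
#'
#' ICC(2,1): single-measure reliability under a two-way random-effects model
#' with absolute agreement, the conservative choice for test-retest data
#' because systematic differences between sessions count as disagreement.
#' Computed from the two-way ANOVA mean squares of the `units x sessions`
#' matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param mat Numeric matrix, `n` units (rows) by `k` sessions/raters
#'   (columns); `n >= 3`, `k >= 2`, no missing cells.
#' @return List with `icc`, the mean squares (`msr`, `msc`, `mse`), and
#'   `classification` (`"excellent"` > 0.75, `"good"` 0.60-0.74, `"fair"`
#'   0.40-0.59, `"poor"` < 0.40). A constant matrix has no reliability
#'   decomposition and returns `icc = NA` with classification
#'   `"undefined"`.
#' @examples
#' m <- cbind(1:10, 1:10 + rnorm(10, 0, 0.1))
#' icc_agreement(m)$icc
#' @export
icc_agreement <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 3, k >= 2, !anyNA(mat))
  if (stats::sd(as.vector(mat)) == 0) {
    return(list(icc = NA_real_, msr = 0, msc = 0, mse = 0,
                classification = "undefined"))
  }
  grand <- mean(mat)
  ssr <- k * sum((rowMeans(mat) - grand)^2)
  ssc <- n * sum((colMeans(mat) - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  cls <- if (icc > 0.75) "excellent" else if (icc >= 0.60) "good"
         else if (icc >= 0.40) "fair" else "poor"
  list(icc = icc, msr = msr, msc = msc, mse = mse, classification = cls)
}

#' Full agreement analysis of paired measurements
#'
#' Convenience wrapper combining the normality-gated paired difference test,
#' the Bland-Altman limits and the ICC(2,1) for one pair of measurement
#' sessions.
#'
#' @inheritParams paired_difference_test
#' @param context Free-text tag (e.g. `"inter_study"`, `"intra_operator"`,
#'   `"inter_operator"`).
#' @return List of class `agreement_result` with elements `context`,
#'   `mean_diff`, `sd_diff`, `p_value`, `test`, `lower`, `upper`, `icc`,
#'   `icc_class`, `n`.
#' @export
agreement_analysis <- function(first, second, context = "inter_study",
                               alpha = 0.05) {
  pd <- paired_difference_test(first, second, alpha = alpha)
  ba <- bland_altman(first, second)
  ic <- icc_agreement(cbind(first, second))
  structure(list(context = context, mean_diff = pd$mean_diff,
                 sd_diff = pd$sd_diff, p_value = pd$p_value, test = pd$test,
                 lower = ba$lower, upper = ba$upper, icc = ic$icc,
                 icc_class = ic$classification, n = pd$n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s agreement (n = %d): diff %.2f +/- %.2f ms, p = %.3f (%s)\n",
              x$context, x$n, x$mean_diff, x$sd_diff, x$p_value, x$test))
  cat(sprintf("  Bland-Altman limits [%.2f, %.2f]; ICC = %.3f (%s)\n",
              x$lower, x$upper, x$icc, x$icc_class))
  invisible(x)
}
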