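test_that("identical pairs are a degenerate case with p = 1", {
  x <- c(30, 31, 32, 33)
  r <- paired_difference_test(x, x)
  expect_equal(r$p_value, 1)
  expect_equal(r$test, "degenerate")
  expect_equal(r$mean_diff, 0)
})

test_that("normality gate selects the paired t for normal differences", {
  set.seed(1)
  first <- rnorm(10, 30, 2)
  second <- first - rnorm(10, 0, 1)
  r <- paired_difference_test(first, second)
  expect_equal(r$test, "paired_t")
  expect_equal(r$p_value, t.test(first, second, paired = TRUE)$p.value)
})

test_that("paired-test p-values are uniform under the null (KS over seeds)", {
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    a <- rnorm(10)
    paired_difference_test(a, a - rnorm(10))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gate consistency: normal data mostly t, heavy-tailed mostly Wilcoxon", {
  set.seed(4)
  normal_tests <- replicate(200, paired_difference_test(rnorm(20), rep(0, 20))$test)
  expect_gt(mean(normal_tests == "paired_t"), 0.85)  # gate misfires ~5% by design
  set.seed(3)
  cauchy_tests <- replicate(200, paired_difference_test(rcauchy(20), rep(0, 20))$test)
  expect_gt(mean(cauchy_tests == "wilcoxon"), 0.6)
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  # differences {-1, 0, 1}: SD = 1, limits exactly +/- 1.96
  ba <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$lower, ba$upper), c(-1.96, 1.96))
  # identical pairs: limits collapse to [0, 0]
  ba0 <- bland_altman(c(3, 4, 5), c(3, 4, 5))
  expect_equal(c(ba0$bias, ba0$lower, ba0$upper), c(0, 0, 0))
})

test_that("limits are exactly symmetric about the bias", {
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(15, 34, 3); b <- a - rnorm(15, 0.5, 1)
    ba <- bland_altman(a, b)
    expect_equal(ba$upper - ba$bias, ba$bias - ba$lower, tolerance = 1e-12)
    expect_true(ba$lower <= ba$bias && ba$bias <= ba$upper)
  }
})

test_that("global inter-study variability of 0.88 ms implies ~1.73 ms limits", {
  # reported global repeatability: bias 0.00 +/- 0.88 -> limits +/- 1.73
  expect_equal(1.96 * 0.88, 1.7248, tolerance = 1e-12)
  expect_equal(round(1.96 * 0.88, 2), 1.72)
  set.seed(12)
  d <- rnorm(10); d <- (d - mean(d)) / sd(d) * 0.88  # bias 0, SD 0.88 exactly
  ba <- bland_altman(d, rep(0, 10))
  expect_equal(ba$upper, 1.96 * 0.88, tolerance = 1e-12)
})

test_that("ICC(2,1) matches the aov mean-squares decomposition on a toy matrix", {
  m <- matrix(c(9, 8, 7, 10, 8.5, 8.2, 6.9, 9.4), 4, 2)
  df <- data.frame(y = as.vector(m), unit = factor(rep(1:4, 2)),
                   session = factor(rep(1:2, each = 4)))
  av <- summary(aov(y ~ unit + session, data = df))[[1]]
  msr <- av["unit", "Mean Sq"]; msc <- av["session", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / 4)
  r <- icc_agreement(m)
  expect_equal(r$icc, oracle, tolerance = 1e-12)
  expect_equal(r$msr, msr, tolerance = 1e-12)
  expect_equal(r$mse, mse, tolerance = 1e-12)
})

test_that("ICC is 1 for duplicated columns and ~0 for independent columns", {
  x <- rnorm(20, 30, 3)
  expect_equal(icc_agreement(cbind(x, x))$icc, 1, tolerance = 1e-12)
  set.seed(7)
  r <- icc_agreement(cbind(rnorm(200), rnorm(200)))$icc
  expect_lt(abs(r), 0.15)
})

test_that("ICC is shift-invariant but penalizes a systematic column offset", {
  set.seed(20)
  x <- rnorm(30, 30, 3)
  base <- cbind(x, x + rnorm(30, 0, 0.5))
  expect_equal(icc_agreement(base + 100)$icc, icc_agreement(base)$icc,
               tolerance = 1e-9)
  iccs <- sapply(c(0, 1, 3, 6), function(off) {
    icc_agreement(cbind(base[, 1], base[, 2] + off))$icc
  })
  expect_true(all(diff(iccs) < 0))
  expect_equal(icc_agreement(matrix(5, 4, 2))$classification, "undefined")
})

test_that("agreement_analysis combines test, limits and ICC coherently", {
  set.seed(2)
  coh <- generate_segmental_cohort(cohort_design(n_subjects = 10), seed = 2)
  repeat_coh <- simulate_repeat_measurement(coh, noise_sd = 0.6, seed = 3)
  r <- agreement_analysis(global_t2star(coh), global_t2star(repeat_coh))
  expect_true(r$test %in% c("paired_t", "wilcoxon"))
  expect_gt(r$p_value, 0.05)       # no systematic difference was simulated
  expect_gt(r$icc, 0.75)           # noise SD well below between-subject SD
  expect_lt(r$lower, r$mean_diff)
  expect_gt(r$upper, r$mean_diff)
})
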