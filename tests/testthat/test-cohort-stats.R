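test_that("stratified means recombine to the overall mean (n-weighted)", {
  coh <- generate_segmental_cohort(seed = 41)
  overall <- normative_summary(coh)
  for (strat in c("age_bin", "sex")) {
    tab <- normative_summary(coh, strat)
    expect_equal(sum(tab$n), overall$n)
    expect_equal(sum(tab$n * tab$mean_t2star) / sum(tab$n),
                 overall$mean_t2star, tolerance = 1e-12)
  }
})

test_that("slice summary averages segments 1-6, 7-12, 13-16 per subject", {
  t2 <- matrix(rep(c(rep(30, 6), rep(34, 6), rep(38, 4)), 3), nrow = 3,
               byrow = TRUE)
  coh <- make_cohort(t2)
  tab <- normative_summary(coh, "slice")
  expect_equal(tab$stratum, c("basal", "mid", "apical"))
  expect_equal(tab$mean_t2star, c(30, 34, 38))
  expect_equal(tab$n, rep(3, 3))
})

test_that("a zero-SD cohort corrected by its own map has equal slice means", {
  spec <- segment_distribution(sd_r2star = rep(0, 16))
  coh <- generate_segmental_cohort(cohort_design(n_subjects = 8), spec, seed = 1)
  map <- estimate_correction_factors(coh)
  corrected <- apply_correction(coh, map)
  tab <- normative_summary(corrected, "slice")
  ms <- 1000 / mean(midseptal_r2star(coh))
  expect_equal(tab$mean_t2star, rep(ms, 3), tolerance = 1e-12)
  expect_equal(max(tab$sd_t2star), 0, tolerance = 1e-12)
})

test_that("empty strata are reported with n = 0 and no statistics", {
  coh <- generate_segmental_cohort(cohort_design(
    n_subjects = 10, age_bins = cbind(20, 30)), seed = 4)
  tab <- normative_summary(coh, "age_bin")
  expect_equal(tab$n[1], 10)
  expect_true(all(tab$n[-1] == 0))
  expect_true(all(is.na(tab$mean_t2star[-1])))
})

test_that("correlate recovers exact linear dependence with any method", {
  x <- seq(1, 10, 0.5)
  for (m in c("pearson", "spearman", "auto")) {
    r <- correlate(x, 2 * x + 1, method = m)
    expect_equal(r$r, 1, tolerance = 1e-9)
  }
  expect_error(correlate(x, rep(3, length(x))), "constant")
})

test_that("correlation type-I error is near the nominal 5% under the null", {
  set.seed(11)
  rej <- mean(replicate(1000, correlate(rnorm(50), rnorm(50))$p_value < 0.05))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})

test_that("group comparison gates between Student t and Mann-Whitney", {
  set.seed(6)
  a <- rnorm(25, 34, 2.5); b <- rnorm(25, 34, 2.5)
  r <- group_compare(a, b)
  expect_equal(r$test, "student_t")
  expect_equal(r$p_value, t.test(a, b, var.equal = TRUE)$p.value)
  skew <- rexp(25)^3
  r2 <- group_compare(skew, rexp(25)^3)
  expect_equal(r2$test, "mann_whitney")
})

test_that("sex has no effect on global T2* in the unconditioned generator", {
  hits <- sapply(1:10, function(s) {
    coh <- generate_segmental_cohort(seed = 500 + s)
    g <- global_t2star(coh)
    group_compare(g[coh$sex == "M"], g[coh$sex == "F"])$p_value < 0.05
  })
  expect_lte(mean(hits), 0.1)
})

test_that("designed wall-thickness sex contrast is strongly detected", {
  hits <- sapply(1:10, function(s) {
    coh <- generate_segmental_cohort(seed = 600 + s)
    wt <- rowMeans(coh[, wall_thickness_columns()])
    group_compare(wt[coh$sex == "M"], wt[coh$sex == "F"])$p_value < 0.001
  })
  expect_gte(mean(hits), 0.8)
})

test_that("multivariable model stays null when no effects are simulated", {
  sig <- sapply(1:20, function(s) {
    coh <- generate_segmental_cohort(seed = 700 + s)
    any(multivariable_model(coh, "global")[
      multivariable_model(coh, "global")$term %in% c("age"), "p_corrected"] < 0.05)
  })
  expect_lte(mean(sig), 0.15)
})

test_that("a planted age effect is recovered with the right sign", {
  slope <- calibrate_age_slope(-0.8)
  d <- cohort_design(n_subjects = 400, age_effect_slope = slope)
  coh <- generate_segmental_cohort(d, seed = 77)
  tab <- multivariable_model(coh, "global")
  age_row <- tab[tab$term == "age", ]
  expect_lt(age_row$estimate, 0)
  expect_lt(age_row$p_corrected, 1e-6)
})

test_that("segmental models use per-segment wall thickness with Bonferroni", {
  coh <- generate_segmental_cohort(cohort_design(n_subjects = 40), seed = 9)
  tab <- multivariable_model(coh, "segment")
  expect_setequal(unique(tab$response), sprintf("segment_%02d", 7:12))
  expect_true(all(tab$p_corrected >= tab$p))
  expect_true(all(tab$p_corrected <= 1))
  expect_error(multivariable_model(coh[, !grepl("^wt_", names(coh))], "segment"),
               "wall-thickness")
})

test_that("per-segment range report reflects inter-subject spread", {
  coh <- generate_segmental_cohort(seed = 13)
  rng <- segment_range(coh)
  expect_equal(nrow(rng), 16)
  expect_true(all(rng$range > 0))
  expect_equal(rng$range, rng$max - rng$min)
})

test_that("a typical default-size cohort shows no combined covariate effect", {
  # weak age effect, no sex or thickness effect, n = 50
  slope <- calibrate_age_slope(-0.29)
  hits <- sapply(1:10, function(s) {
    coh <- generate_segmental_cohort(
      cohort_design(age_effect_slope = slope), seed = 800 + s)
    all(multivariable_model(coh, "global")$p_corrected > 0.05)
  })
  expect_gte(mean(hits), 0.5)  # "no combined effect" is the typical outcome
})
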