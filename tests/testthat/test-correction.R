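test_that("mid-septal reference is the mean of segments 8 and 9 in R2*", {
  t2 <- rep(30, 16)
  t2[8] <- 1000 / 28.5
  t2[9] <- 1000 / 27.5
  expect_equal(midseptal_r2star(t2), 28)
  expect_equal(midseptal_r2star(rep(1000 / 31, 16)), 31)
  coh <- make_cohort(rbind(t2, rep(25, 16)))
  expect_equal(midseptal_r2star(coh), c(28, 40))
})

test_that("correction factors equal averaged per-subject deviations (hand case)", {
  # two subjects: segment 1 at (30, 26) Hz with mid-septal (28, 25)
  r2a <- rep(28, 16); r2a[1] <- 30
  r2b <- rep(25, 16); r2b[1] <- 26
  coh <- make_cohort(rbind(1000 / r2a, 1000 / r2b))
  map <- estimate_correction_factors(coh)
  expect_equal(map$delta_r2star[1], ((30 - 28) + (26 - 25)) / 2)  # 1.5 Hz
  expect_equal(map$delta_r2star[8:9], c(0, 0))
  expect_equal(attr(map, "n_subjects"), 2L)
})

test_that("a cohort equal to its own mid-septum yields an all-zero map", {
  r2 <- matrix(rep(seq(26, 32, length.out = 5), 16), ncol = 16)
  coh <- make_cohort(1000 / r2)
  map <- estimate_correction_factors(coh)
  expect_equal(map$delta_r2star, rep(0, 16), tolerance = 1e-12)
})

test_that("linearity identity: factors equal cohort mean minus mid-septal mean", {
  coh <- generate_segmental_cohort(cohort_design(n_subjects = 30), seed = 17)
  map <- estimate_correction_factors(coh)
  r2 <- cohort_r2star_matrix(coh)
  direct <- colMeans(r2) - mean(rowMeans(r2[, 8:9]))
  expect_equal(map$delta_r2star, unname(direct), tolerance = 1e-12)
  # factors for the reference segments are opposite in sign and sum to ~0
  expect_equal(sum(map$delta_r2star[8:9]), 0, tolerance = 1e-12)
})

test_that("self-correction closure equalizes corrected segmental means", {
  coh <- generate_segmental_cohort(cohort_design(n_subjects = 40), seed = 23)
  map <- estimate_correction_factors(coh)
  corrected <- apply_correction(coh, map)
  rc <- cohort_r2star_matrix(corrected)
  ms <- mean(midseptal_r2star(coh))
  expect_equal(unname(colMeans(rc)), rep(ms, 16), tolerance = 1e-12)
})

test_that("correction arithmetic works in the R2* domain (hand case)", {
  map0 <- segt2star:::new_correction_map(rep(0, 16), 1, "test")
  expect_equal(apply_correction(rep(25, 16), map0), rep(25, 16))
  map8 <- segt2star:::new_correction_map(rep(8, 16), 1, "test")
  # native 25 ms = 40 Hz; minus 8 Hz = 32 Hz = 31.25 ms
  expect_equal(apply_correction(rep(25, 16), map8), rep(31.25, 16))
})

test_that("corrected T2* increases strictly with the factor at fixed native value", {
  native <- rep(30, 16)
  vals <- sapply(seq(-5, 8, length.out = 10), function(f) {
    m <- segt2star:::new_correction_map(rep(f, 16), 1, "test")
    apply_correction(native, m)[1]
  })
  expect_true(all(diff(vals) > 0))
  m2 <- segt2star:::new_correction_map(rep(2, 16), 1, "test")
  expect_true(all(apply_correction(native, m2) > native))  # positive factor raises T2*
})

test_that("uncorrectable segments (corrected R2* <= 0) become NA with a warning", {
  native <- rep(100, 16)  # 10 Hz
  m <- segt2star:::new_correction_map(rep(12, 16), 1, "test")
  expect_warning(out <- apply_correction(native, m), "uncorrectable")
  expect_true(all(is.na(out)))
})

test_that("incomplete records are excluded from factor estimation", {
  coh <- generate_segmental_cohort(cohort_design(n_subjects = 6), seed = 2)
  coh$t2s_seg03[2] <- NA
  expect_message(map <- estimate_correction_factors(coh), "1 subject")
  expect_equal(attr(map, "n_subjects"), 5L)
  expect_error(estimate_correction_factors(coh[2, ]), "at least 2")
})

test_that("held-out cohorts show reduced segmental spread after correction", {
  factors <- reference_correction_factors("cvi42")
  for (s in 1:5) {
    held_out <- generate_segmental_cohort(cohort_design(n_subjects = 50),
                                          seed = 300 + s)
    corrected <- apply_correction(held_out, factors)
    native_means <- colMeans(cohort_r2star_matrix(held_out))
    corr_means <- colMeans(cohort_r2star_matrix(corrected))
    expect_lt(diff(range(corr_means)), diff(range(native_means)))
  }
})

test_that("pooled-summary t-test matches stats::t.test on raw data", {
  set.seed(55)
  a <- rnorm(20, 30, 5); b <- rnorm(12, 27, 4)
  ours <- t_test_from_summary(mean(a), sd(a), 20, mean(b), sd(b), 12)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
})

test_that("identical summaries give t = 0, p = 1", {
  r <- t_test_from_summary(30, 5, 20, 30, 5, 20)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  cmp <- compare_cohorts_segmental(reference_segmental_r2star("cvi42"),
                                   reference_segmental_r2star("cvi42"))
  expect_true(all(cmp$t == 0 & cmp$p == 1))
})

test_that("correction maps round-trip through CSV + JSON sidecar", {
  map <- reference_correction_factors("cvi42")
  path <- withr::local_tempfile(fileext = ".csv")
  write_correction_map(map, path)
  back <- read_correction_map(path)
  expect_equal(back$delta_r2star, map$delta_r2star)
  expect_equal(attr(back, "n_subjects"), attr(map, "n_subjects"))
})
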