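#' Normative summary of a cohort
#'
#' Mean and sample SD of a per-subject scalar, optionally stratified. The
#' scalar is the global T2* (mean of the 16 segments) for `"none"`,
#' `"age_bin"` and `"sex"` stratifications; for `"slice"` the strata are the
#' basal, mid-ventricular and apical slices, each subject contributing its
#' per-slice mean.
#'
#' @param cohort Cohort data frame (see [segment_columns()]).
#' @param stratify_by `"none"`, `"age_bin"`, `"sex"` or `"slice"`.
#' @param age_bins Two-column `[lo, hi)` matrix used for `"age_bin"`
#'   (default the five decades 20-69; the last bin is closed above).
#' @return Data frame with `stratum`, `n`, `mean_t2star`, `sd_t2star` (ms).
#'   Empty strata are reported with `n = 0` and `NA` statistics.
#' @export
normative_summary <- function(cohort,
                              stratify_by = c("none", "age_bin", "sex", "slice"),
                              age_bins = cbind(seq(20, 60, 10), seq(30, 70, 10))) {
  stratify_by <- match.arg(stratify_by)
  g <- global_t2star(cohort)

  summarise <- function(values, labels, levels) {
    rows <- lapply(levels, function(lv) {
      v <- values[labels == lv]
      data.frame(stratum = lv, n = length(v),
                 mean_t2star = if (length(v)) mean(v) else NA_real_,
                 sd_t2star = if (length(v) > 1) stats::sd(v) else
                   if (length(v) == 1) 0 else NA_real_)
    })
    do.call(rbind, rows)
  }

  switch(stratify_by,
    none = data.frame(stratum = "all", n = length(g),
                      mean_t2star = mean(g), sd_t2star = stats::sd(g)),
    sex = summarise(g, cohort$sex, sort(unique(cohort$sex))),
    age_bin = {
      lab <- sprintf("%d-%d", age_bins[, 1], age_bins[, 2] - 1)
      idx <- rep(NA_integer_, length(g))
      for (b in seq_len(nrow(age_bins))) {
        hit <- cohort$age_years >= age_bins[b, 1] &
          (cohort$age_years < age_bins[b, 2] |
             (b == nrow(age_bins) & cohort$age_years <= age_bins[b, 2]))
        idx[hit] <- b
      }
      summarise(g, lab[idx], lab)
    },
    slice = {
      sl <- slice_t2star(cohort)
      vals <- c(sl$basal, sl$mid, sl$apical)
      labs <- rep(c("basal", "mid", "apical"), each = nrow(sl))
      summarise(vals, labs, c("basal", "mid", "apical"))
    })
}

#' Correlation with normality-gated method choice
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk normality
#' test at `alpha`, Spearman otherwise (`method = "auto"`); either method
#' can be forced.
#'
#' @param x,y Numeric vectors (>= 3 complete pairs).
#' @param method `"auto"` (default), `"pearson"` or `"spearman"`.
#' @param alpha Significance level of the normality gate.
#' @return List with `r`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant variable")
  }
  if (method == "auto") {
    normal <- stats::shapiro.test(x)$p.value >= alpha &&
      stats::shapiro.test(y)$p.value >= alpha
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, method = method,
       n = length(x))
}

#' Two-group comparison with normality gating
#'
#' Student's unpaired (pooled-variance) t-test when both groups pass the
#' Shapiro-Wilk test at `alpha`, Mann-Whitney otherwise.
#'
#' @param a,b Numeric vectors (each >= 3 values).
#' @param alpha Significance level of the normality gate.
#' @return List with `p_value`, `test`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
group_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 3, length(b) >= 3, !anyNA(a), !anyNA(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(p_value = if (mean(a) == mean(b)) 1 else 0,
                test = "degenerate", mean_a = mean(a), mean_b = mean(b),
                n_a = length(a), n_b = length(b)))
  }
  normal <- stats::sd(a) > 0 && stats::sd(b) > 0 &&
    stats::shapiro.test(a)$p.value >= alpha &&
    stats::shapiro.test(b)$p.value >= alpha
  if (normal) {
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    test <- "student_t"
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    test <- "mann_whitney"
  }
  list(p_value = p, test = test, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Multivariable linear model of T2* on demographics
#'
#' Ordinary least-squares model of a T2* response on age, sex and (where
#' available) wall thickness, the covariate-adjusted analysis customary for
#' normative mapping cohorts. With `response = "global"` one model of the
#' global T2* on age and sex is fitted (plus mean mid-ventricular wall
#' thickness if present); with `response = "segment"` one model per
#' mid-ventricular segment (7-12) is fitted using that segment's own wall
#' thickness, and p-values are Bonferroni-corrected across the fitted
#' responses.
#'
#' @param cohort Cohort data frame.
#' @param response `"global"` or `"segment"`.
#' @param segments Segment ids to model when `response = "segment"`
#'   (subset of 7:12, where wall thickness exists).
#' @return Data frame with `response`, `term`, `estimate`, `std_error`,
#'   `p`, `p_corrected`; the Bonferroni family size is the number of
#'   responses fitted.
#' @export
multivariable_model <- function(cohort, response = c("global", "segment"),
                                segments = 7:12) {
  response <- match.arg(response)
  has_wt <- all(wall_thickness_columns() %in% names(cohort))
  coef_rows <- function(fit, label) {
    sm <- summary(fit)$coefficients
    sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    data.frame(response = label, term = rownames(sm),
               estimate = sm[, 1], std_error = sm[, 2], p = sm[, 4],
               row.names = NULL)
  }
  if (response == "global") {
    dat <- data.frame(y = global_t2star(cohort), age = cohort$age_years,
                      sex = factor(cohort$sex))
    form <- y ~ age + sex
    if (has_wt) {
      dat$wall_thickness <- rowMeans(cohort[, wall_thickness_columns()])
      form <- y ~ age + sex + wall_thickness
    }
    out <- coef_rows(stats::lm(form, data = dat), "global")
    out$p_corrected <- pmin(1, out$p)   # single response, family of 1
    return(out)
  }
  stopifnot(all(segments %in% 7:12))
  if (!has_wt) stop("segmental models require wall-thickness columns")
  t2 <- cohort_t2star_matrix(cohort)
  rows <- lapply(segments, function(k) {
    dat <- data.frame(y = t2[, k], age = cohort$age_years,
                      sex = factor(cohort$sex),
                      wall_thickness = cohort[[sprintf("wt_seg%02d", k)]])
    coef_rows(stats::lm(y ~ age + sex + wall_thickness, data = dat),
              sprintf("segment_%02d", k))
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- pmin(1, out$p * length(segments))
  out
}

#' Per-segment range across subjects
#'
#' The max - min spread of each segment's T2* across the cohort, a simple
#' display of inter-individual segmental variability.
#'
#' @param cohort Cohort data frame.
#' @return Data frame with `segment`, `aha_name`, `min`, `max`, `range` (ms).
#' @export
segment_range <- function(cohort) {
  t2 <- cohort_t2star_matrix(cohort)
  data.frame(segment = 1:16, aha_name = aha_segment_names(),
             min = apply(t2, 2, min, na.rm = TRUE),
             max = apply(t2, 2, max, na.rm = TRUE),
             range = apply(t2, 2, function(v) diff(range(v, na.rm = TRUE))))
}
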