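#' Column names of the segmental T2* table
#'
#' Cohort tables carry one row per subject with columns `subject_id`,
#' `age_years`, `sex`, the 16 segmental T2* values `t2s_seg01`..`t2s_seg16`
#' (ms) and, optionally, mid-ventricular wall thickness `wt_seg07`..`wt_seg12`
#' (mm).
#'
#' @return Character vector `t2s_seg01`..`t2s_seg16`.
#' @export
segment_columns <- function() sprintf("t2s_seg%02d", 1:16)

#' @rdname segment_columns
#' @export
wall_thickness_columns <- function() sprintf("wt_seg%02d", 7:12)

#' Segmental T2* values of a cohort as a matrix
#'
#' @param cohort Cohort data frame (see [segment_columns()]).
#' @return Numeric matrix, subjects x 16 segments (ms).
#' @export
cohort_t2star_matrix <- function(cohort) {
  cols <- segment_columns()
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort table lacks segmental columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(cohort[, cols])
}

#' Segmental R2* values of a cohort as a matrix
#'
#' @inheritParams cohort_t2star_matrix
#' @return Numeric matrix, subjects x 16 segments (Hz).
#' @export
cohort_r2star_matrix <- function(cohort) t2star_to_r2star(cohort_t2star_matrix(cohort))

#' Per-segment distribution of R2* in a simulated population
#'
#' Holds the population mean and SD of R2* (Hz) for each of the 16 AHA
#' segments. The defaults are the normative black-blood MEGE cohort values of
#' [reference_segmental_r2star()] (`"cvi42"`), so a default synthetic cohort
#' reproduces that population's segmental structure.
#'
#' @param mean_r2star,sd_r2star Numeric vectors of length 16: segment means
#'   (Hz, > 0) and SDs (Hz, >= 0).
#' @return An object of class `segment_distribution`.
#' @export
segment_distribution <- function(mean_r2star = reference_segmental_r2star("cvi42")$mean_r2star,
                                 sd_r2star = reference_segmental_r2star("cvi42")$sd_r2star) {
  stopifnot(length(mean_r2star) == 16, length(sd_r2star) == 16)
  if (any(mean_r2star <= 0)) stop("all segment mean R2* must be positive")
  if (any(sd_r2star < 0)) stop("segment SDs must be non-negative")
  structure(list(mean_r2star = as.numeric(mean_r2star),
                 sd_r2star = as.numeric(sd_r2star)),
            class = "segment_distribution")
}

#' Design of a simulated healthy cohort
#'
#' The default design mirrors the normative study population: 50 subjects,
#' equal numbers of males and females, and equal counts in each of five age
#' decades from 20 to 69 years.
#'
#' @param n_subjects Number of subjects (> 0).
#' @param sex_balance Proportion of males (subjects are assigned
#'   deterministically, alternating within each age bin, so the balance is
#'   exact whenever the counts allow).
#' @param age_bins Two-column matrix of `[lo, hi)` age bins in years.
#' @param age_effect_slope Additive shift of every segmental T2* (ms) per
#'   year of age, centred on the design's mid-age so the cohort mean is
#'   unchanged. Default 0 (no age effect). See [calibrate_age_slope()].
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 50, sex_balance = 0.5,
                          age_bins = cbind(seq(20, 60, 10), seq(30, 70, 10)),
                          age_effect_slope = 0) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("`n_subjects` must be positive")
  stopifnot(sex_balance >= 0, sex_balance <= 1)
  age_bins <- as.matrix(age_bins)
  stopifnot(ncol(age_bins) == 2, all(age_bins[, 2] > age_bins[, 1]))
  structure(list(n_subjects = as.integer(n_subjects), sex_balance = sex_balance,
                 age_bins = age_bins, age_effect_slope = age_effect_slope),
            class = "cohort_design")
}

#' Generate a synthetic segmental cohort
#'
#' Draws per-subject segmental R2* values independently per segment from
#' normal distributions with the means and SDs of `spec`, truncated to
#' `mean +/- truncate_sd * sd` (and to positive values), then converts to
#' T2*. Symmetric truncation keeps each segment's population mean exactly at
#' the specified value while excluding non-physiological extremes; without a
#' lower bound the reciprocal 1000/R2* would have no finite mean and cohort
#' summaries would be dominated by rare near-zero draws.
#'
#' Ages are drawn uniformly within each design bin with equal per-bin counts
#' (remainders spread over the first bins); sex alternates within each bin so
#' the sex balance is exact. If `design$age_effect_slope` is non-zero, a
#' subject-level shift `slope * (age - mid_age)` is added to all 16 segmental
#' T2* values. Wall thickness for segments 7-12 is drawn from sex-specific
#' normal distributions typical of healthy adults.
#'
#' @param design A [cohort_design()].
#' @param spec A [segment_distribution()].
#' @param seed Integer seed; identical inputs and seed give identical tables.
#' @param truncate_sd Truncation half-width in SD units (default 3).
#' @param wall_thickness Logical; include `wt_seg07`..`wt_seg12` columns.
#' @return Cohort data frame (see [segment_columns()]).
#' @examples
#' coh <- generate_segmental_cohort(cohort_design(n_subjects = 10), seed = 1)
#' mean(global_t2star(coh))
#' @export
generate_segmental_cohort <- function(design = cohort_design(),
                                      spec = segment_distribution(),
                                      seed = NULL, truncate_sd = 3,
                                      wall_thickness = TRUE) {
  stopifnot(inherits(design, "cohort_design"), inherits(spec, "segment_distribution"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects

  # ages and sexes: equal bin occupancy, alternating sex within bin
  nb <- nrow(design$age_bins)
  per_bin <- rep(n %/% nb, nb)
  if (n %% nb) per_bin[seq_len(n %% nb)] <- per_bin[seq_len(n %% nb)] + 1L
  bin_of <- rep(seq_len(nb), per_bin)
  age <- stats::runif(n, design$age_bins[bin_of, 1], design$age_bins[bin_of, 2])
  sex <- character(n)
  for (b in seq_len(nb)) {
    idx <- which(bin_of == b)
    nm <- round(length(idx) * design$sex_balance)
    sx <- rep(c("M", "F"), length.out = length(idx))
    if (sum(sx == "M") != nm) sx <- c(rep("M", nm), rep("F", length(idx) - nm))
    sex[idx] <- sx
  }

  r2 <- matrix(NA_real_, n, 16)
  for (k in 1:16) {
    mu <- spec$mean_r2star[k]; s <- spec$sd_r2star[k]
    if (s == 0) { r2[, k] <- mu; next }
    lo <- max(0, mu - truncate_sd * s); hi <- mu + truncate_sd * s
    draws <- stats::rnorm(n, mu, s)
    bad <- draws <= lo | draws >= hi
    while (any(bad)) {
      draws[bad] <- stats::rnorm(sum(bad), mu, s)
      bad <- draws <= lo | draws >= hi
    }
    r2[, k] <- draws
  }
  t2 <- 1000 / r2

  if (design$age_effect_slope != 0) {
    mid_age <- mean(range(design$age_bins))
    t2 <- t2 + design$age_effect_slope * (age - mid_age)
    if (any(t2 <= 0)) stop("age effect drove a segmental T2* non-positive")
  }

  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age_years = age, sex = sex)
  out[segment_columns()] <- as.data.frame(t2)

  if (wall_thickness) {
    # healthy mid-ventricular wall thickness (mm): males thicker by ~1.6-1.8
    wt_m <- c(6.8, 7.1, 7.5, 6.3, 6.0, 5.8)
    wt_f <- c(5.0, 5.3, 5.7, 4.7, 4.4, 4.7)
    wt_sd <- 1.1
    for (i in 1:6) {
      mu <- ifelse(sex == "M", wt_m[i], wt_f[i])
      out[[wall_thickness_columns()[i]]] <- pmax(1, stats::rnorm(n, mu, wt_sd))
    }
  }
  out
}

#' Calibrate the age-effect slope to a target correlation
#'
#' Computes the T2* shift per year that gives a requested population Pearson
#' correlation between age and global T2* under the design and segment
#' distribution. The global-T2* variance is obtained by numerical integration
#' of the truncated-normal reciprocal moments, and the age variance from the
#' uniform-within-bin design, so
#' `r = slope * sd_age / sqrt(slope^2 sd_age^2 + var_global)`.
#'
#' @param target_r Desired population Pearson correlation in (-1, 1).
#' @inheritParams generate_segmental_cohort
#' @return Slope in ms of global T2* per year.
#' @examples
#' s <- calibrate_age_slope(-0.29)
#' d <- cohort_design(age_effect_slope = s)
#' @export
calibrate_age_slope <- function(target_r, design = cohort_design(),
                                spec = segment_distribution(), truncate_sd = 3) {
  stopifnot(abs(target_r) < 1)
  if (target_r == 0) return(0)
  mom <- vapply(1:16, function(k) {
    mu <- spec$mean_r2star[k]; s <- spec$sd_r2star[k]
    if (s == 0) return(c(1000 / mu, 0))
    lo <- max(0, mu - truncate_sd * s); hi <- mu + truncate_sd * s
    z <- stats::pnorm(hi, mu, s) - stats::pnorm(lo, mu, s)
    m1 <- stats::integrate(function(x) (1000 / x) * stats::dnorm(x, mu, s) / z,
                           lo, hi, rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(x) (1000 / x)^2 * stats::dnorm(x, mu, s) / z,
                           lo, hi, rel.tol = 1e-10)$value
    c(m1, m2 - m1^2)
  }, numeric(2))
  var_global <- sum(mom[2, ]) / 256   # independent segments, mean of 16
  # age: uniform within bins, equal occupancy
  bins <- design$age_bins
  m_b <- rowMeans(bins)
  v_b <- (bins[, 2] - bins[, 1])^2 / 12
  var_age <- mean(v_b) + mean(m_b^2) - mean(m_b)^2
  sign(target_r) * abs(target_r) / sqrt(1 - target_r^2) *
    sqrt(var_global / var_age)
}

#' Simulate a repeat measurement of a cohort
#'
#' Adds independent zero-mean Gaussian measurement noise to every segmental
#' T2* value, emulating a second scan (or a re-analysis) of the same
#' subjects for reproducibility studies.
#'
#' @param cohort Cohort data frame.
#' @param noise_sd Measurement noise SD (ms) per segment.
#' @param seed Optional integer seed.
#' @return Cohort data frame with perturbed segmental values.
#' @export
simulate_repeat_measurement <- function(cohort, noise_sd, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- cohort_t2star_matrix(cohort)
  m <- m + stats::rnorm(length(m), 0, noise_sd)
  if (any(m <= 0)) stop("measurement noise drove a segmental T2* non-positive")
  cohort[segment_columns()] <- as.data.frame(m)
  cohort
}

#' Read / write segmental cohort tables
#'
#' Plain-CSV serialization of the cohort table format of [segment_columns()].
#'
#' @param path File path.
#' @param cohort Cohort data frame.
#' @return `read_cohort_csv` returns the validated data frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_t2star_matrix(out)  # validates presence of the 16 columns
  out
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
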