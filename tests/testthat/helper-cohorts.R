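# Build a cohort table from a fixed matrix of segmental T2* values (ms):
# one row per subject, deterministic demographics.
make_cohort <- function(t2star, age = NULL, sex = NULL) {
  if (is.vector(t2star)) t2star <- matrix(t2star, nrow = 1)
  n <- nrow(t2star)
  stopifnot(ncol(t2star) == 16)
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age_years = if (is.null(age)) seq(25, 65, length.out = n) else age,
                    sex = if (is.null(sex)) rep(c("M", "F"), length.out = n) else sex)
  out[segment_columns()] <- as.data.frame(t2star)
  out
}

# Cohort in which every subject's segmental R2* equals a given 16-vector (Hz).
make_constant_r2star_cohort <- function(r2star, n = 4) {
  make_cohort(matrix(rep(1000 / r2star, each = n), nrow = n))
}
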