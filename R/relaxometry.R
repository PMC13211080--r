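#' Convert between T2* (ms) and R2* (Hz)
#'
#' The relaxation rate R2* is the reciprocal of the relaxation time T2*:
#' `R2* [Hz] = 1000 / T2* [ms]`. The two functions are exact inverses.
#'
#' @param t2star,r2star Positive numeric vectors (ms and Hz respectively).
#' @return Numeric vector of the converted quantity.
#' @examples
#' t2star_to_r2star(20)   # 50 Hz
#' r2star_to_t2star(40)   # 25 ms
#' @export
t2star_to_r2star <- function(t2star) {
  if (!is.numeric(t2star) || any(!is.na(t2star) & t2star <= 0)) {
    stop("T2* values must be positive")
  }
  1000 / t2star
}

#' @rdname t2star_to_r2star
#' @export
r2star_to_t2star <- function(r2star) {
  if (!is.numeric(r2star) || any(!is.na(r2star) & r2star <= 0)) {
    stop("R2* values must be positive")
  }
  1000 / r2star
}

#' Fit a mono-exponential T2* decay to a multi-echo signal
#'
#' Fits `S(TE) = S0 * exp(-TE / T2*)` to one decay sample. The log-linear
#' method is an ordinary least-squares fit of `log(S)` on TE; the nonlinear
#' method is Levenberg-Marquardt least squares on the signal scale,
#' initialized from the log-linear estimate. The optional noise-floor rule
#' drops trailing echoes whose signal has fallen below `2 * sigma`, the usual
#' guard against the rectified-noise plateau of magnitude images.
#'
#' @param echo_times Strictly increasing echo times (ms).
#' @param signals Non-negative signal intensities, same length.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @param truncation `"none"` (default) or `"noise_floor"`.
#' @param sigma Noise standard deviation, required for `"noise_floor"`.
#'
#' @return An object of class `t2star_fit`: a list with `t2star` (ms), `s0`,
#'   `r2star` (Hz), `r_squared`, `n_echoes_used`, `method` and `valid`.
#'   Non-decaying or under-determined samples return `valid = FALSE` with
#'   `t2star = NA` rather than an error, so that single bad pixels do not
#'   abort a map fit.
#' @examples
#' te <- echo_times(echo_protocol())
#' fit_monoexponential(te, 1000 * exp(-te / 30))$t2star  # 30
#' @export
fit_monoexponential <- function(echo_times, signals,
                                method = c("loglinear", "nonlinear"),
                                truncation = c("none", "noise_floor"),
                                sigma = NULL) {
  method <- match.arg(method)
  truncation <- match.arg(truncation)
  stopifnot(is.numeric(echo_times), is.numeric(signals),
            length(echo_times) == length(signals))
  if (any(diff(echo_times) <= 0)) stop("echo times must be strictly increasing")
  if (any(signals < 0)) stop("signals must be non-negative")

  if (truncation == "noise_floor") {
    if (is.null(sigma) || sigma < 0) {
      stop("`sigma` must be supplied for noise_floor truncation")
    }
    above <- which(signals >= 2 * sigma)
    keep <- if (length(above)) seq_len(max(above)) else integer(0)
    echo_times <- echo_times[keep]
    signals <- signals[keep]
  }

  invalid <- function() {
    structure(list(t2star = NA_real_, s0 = NA_real_, r2star = NA_real_,
                   r_squared = NA_real_, n_echoes_used = 0L,
                   method = method, valid = FALSE),
              class = "t2star_fit")
  }

  # log-linear always computed: it is the estimator or the starting value
  pos <- signals > 0
  if (sum(pos) < 3) return(invalid())
  te <- echo_times[pos]
  y <- log(signals[pos])
  fit <- stats::lm.fit(cbind(1, te), y)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0) return(invalid())
  t2_ll <- -1 / slope
  s0_ll <- exp(unname(fit$coefficients[1]))

  if (method == "loglinear") {
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
    return(structure(list(t2star = unname(t2_ll), s0 = unname(s0_ll),
                          r2star = unname(1000 / t2_ll),
                          r_squared = max(0, min(1, r2)),
                          n_echoes_used = length(te), method = method,
                          valid = TRUE),
                     class = "t2star_fit"))
  }

  # nonlinear: all (including zero) signals enter the residual
  dat <- data.frame(te = echo_times, s = signals)
  nl <- try(minpack.lm::nlsLM(s ~ s0 * exp(-te / t2), data = dat,
                              start = list(s0 = s0_ll, t2 = t2_ll),
                              lower = c(0, 1e-6),
                              control = minpack.lm::nls.lm.control(maxiter = 200)),
            silent = TRUE)
  if (inherits(nl, "try-error")) return(invalid())
  cf <- stats::coef(nl)
  if (!is.finite(cf[["t2"]]) || cf[["t2"]] <= 0) return(invalid())
  res <- stats::resid(nl)
  ss_tot <- sum((dat$s - mean(dat$s))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(t2star = unname(cf[["t2"]]), s0 = unname(cf[["s0"]]),
                 r2star = unname(1000 / cf[["t2"]]),
                 r_squared = max(0, min(1, r2)),
                 n_echoes_used = nrow(dat), method = method, valid = TRUE),
            class = "t2star_fit")
}

#' @export
print.t2star_fit <- function(x, ...) {
  if (!x$valid) {
    cat("T2* fit: invalid (non-decaying or under-determined sample)\n")
  } else {
    cat(sprintf("T2* fit (%s): T2* = %.3f ms (R2* = %.3f Hz), S0 = %.1f, R^2 = %.4f, %d echoes\n",
                x$method, x$t2star, x$r2star, x$s0, x$r_squared, x$n_echoes_used))
  }
  invisible(x)
}

#' Pixel-wise T2* map from a multi-echo image
#'
#' Applies the log-linear mono-exponential fit independently to every pixel
#' of a multi-echo image (third dimension = echo). The log-linear estimator
#' is vectorized in closed form over all pixels whose signals are all
#' positive; remaining pixels fall back to [fit_monoexponential()]. Pixels
#' with fewer than 3 usable echoes or a non-decaying signal are marked
#' invalid (`NA` in the map).
#'
#' @param image Numeric array `(nx, ny, n_echoes)`.
#' @param echo_times Echo times (ms), length matching `dim(image)[3]`.
#' @param method Fit method passed per pixel; the vectorized closed form is
#'   used only for `"loglinear"`.
#' @return A list with matrices `t2star` (ms), `r_squared`, and logical
#'   `valid`, each `(nx, ny)`.
#' @export
fit_t2star_map <- function(image, echo_times, method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(length(dim(image)) == 3, dim(image)[3] == length(echo_times))
  nx <- dim(image)[1]; ny <- dim(image)[2]; ne <- dim(image)[3]
  sig <- matrix(image, nx * ny, ne)

  t2 <- matrix(NA_real_, nx, ny)
  r2 <- matrix(NA_real_, nx, ny)

  all_pos <- rowSums(sig > 0) == ne
  if (method == "loglinear" && any(all_pos)) {
    y <- log(sig[all_pos, , drop = FALSE])
    te <- echo_times
    tec <- te - mean(te)
    slope <- (y %*% tec) / sum(tec^2)
    ybar <- rowMeans(y)
    fitted_ss <- as.vector(slope)^2 * sum(tec^2)
    tot_ss <- rowSums((y - ybar)^2)
    ok <- is.finite(slope) & slope < 0
    t2v <- rep(NA_real_, sum(all_pos))
    t2v[ok] <- -1 / slope[ok]
    r2v <- ifelse(tot_ss > 0, pmax(0, pmin(1, fitted_ss / tot_ss)), 1)
    r2v[!ok] <- NA_real_
    t2[all_pos] <- t2v
    r2[all_pos] <- r2v
    rest <- which(!all_pos)
  } else {
    rest <- seq_len(nx * ny)
  }
  for (i in rest) {
    f <- fit_monoexponential(echo_times, sig[i, ], method = method)
    if (f$valid) { t2[i] <- f$t2star; r2[i] <- f$r_squared }
  }
  list(t2star = t2, r_squared = r2, valid = is.finite(t2))
}

#' Segment-level mean T2* over a pixel mask
#'
#' The segmental T2* is the arithmetic mean of the per-pixel T2* values
#' inside the segment's region of interest (not a fit of the mean signal);
#' invalid pixels are excluded.
#'
#' @param t2star_map Numeric matrix of per-pixel T2* (ms); `NA` = invalid.
#' @param mask Logical matrix of the same shape.
#' @return A list with `mean`, `sd` (sample SD, ms) and `n_pixels`.
#' @export
segment_mean_t2star <- function(t2star_map, mask) {
  stopifnot(identical(dim(t2star_map), dim(mask)))
  vals <- t2star_map[which(mask)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("mask contains no valid pixels")
  list(mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n_pixels = length(vals))
}

#' Global T2* of a subject
#'
#' The global myocardial T2* is the unweighted arithmetic mean of the 16
#' segmental T2* values, taken in the T2* (ms) domain.
#'
#' @param x Either a numeric vector of 16 segmental T2* values (ms), or a
#'   cohort data frame with columns `t2s_seg01`..`t2s_seg16` (one value per
#'   subject is returned).
#' @return Numeric scalar, or a vector with one element per row of `x`.
#' @export
global_t2star <- function(x) {
  if (is.data.frame(x)) {
    m <- cohort_t2star_matrix(x)
    if (anyNA(m)) stop("all 16 segmental T2* values are required per subject")
    return(rowMeans(m))
  }
  if (!is.numeric(x) || length(x) != 16 || anyNA(x)) {
    stop("expected 16 segmental T2* values")
  }
  mean(x)
}

#' Per-slice mean T2* of each subject
#'
#' Averages segments 1-6 (basal), 7-12 (mid-ventricular) and 13-16 (apical)
#' per subject, in the T2* domain.
#'
#' @param cohort Cohort data frame with `t2s_seg01`..`t2s_seg16` columns.
#' @return Data frame with columns `basal`, `mid`, `apical` (ms).
#' @export
slice_t2star <- function(cohort) {
  m <- cohort_t2star_matrix(cohort)
  data.frame(basal = rowMeans(m[, 1:6, drop = FALSE]),
             mid = rowMeans(m[, 7:12, drop = FALSE]),
             apical = rowMeans(m[, 13:16, drop = FALSE]))
}
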