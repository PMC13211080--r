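#' Geometry of an idealized short-axis phantom
#'
#' Describes a circular left-ventricular cross-section used by the phantom
#' generator and the segment-mask builder: a myocardial annulus between an
#' endocardial and an epicardial radius, centred on the image grid, with the
#' blood pool inside. The contour offset erodes the annulus radially on both
#' sides before segmental ROIs are drawn, the usual guard against epicardial
#' fat and blood-pool contamination.
#'
#' Angles follow the mathematical convention (degrees counterclockwise from
#' the +x axis, y up). `reference_angle` is the angular origin of AHA
#' segment 1 (basal/mid anterior), i.e. the anterior junction with the right
#' ventricle; the default 60 places the anterior sector centre at 90 (top of
#' the image, RV on the left).
#'
#' @param grid_size Image matrix size in pixels (square).
#' @param pixel_spacing Pixel size in mm (default 400 mm FOV / 256 px).
#' @param center Myocardium centre `(x, y)` in pixels; default grid centre.
#' @param endo_radius,epi_radius Endocardial / epicardial radii (mm).
#' @param reference_angle Angular origin of segment 1 (degrees).
#' @param contour_offset Radial erosion applied to both contours (mm).
#' @param s0 Baseline signal at TE = 0 (arbitrary units).
#' @param noise_sigma Noise SD (same units as `s0`).
#' @param noise_model `"rician"` (magnitude MRI, default) or `"gaussian"`.
#' @param blood_signal Mean blood-pool/background signal (default 0,
#'   black-blood acquisition).
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_size = 128, pixel_spacing = 400 / 256,
                             center = NULL, endo_radius = 24, epi_radius = 32,
                             reference_angle = 60, contour_offset = 2,
                             s0 = 1000, noise_sigma = 0,
                             noise_model = c("rician", "gaussian"),
                             blood_signal = 0) {
  noise_model <- match.arg(noise_model)
  stopifnot(grid_size >= 8, pixel_spacing > 0, endo_radius > 0,
            epi_radius > endo_radius, contour_offset >= 0, s0 > 0,
            noise_sigma >= 0, blood_signal >= 0)
  if (endo_radius + contour_offset >= epi_radius - contour_offset) {
    stop("contour offset leaves an empty myocardial annulus")
  }
  if (is.null(center)) center <- c((grid_size + 1) / 2, (grid_size + 1) / 2)
  structure(list(grid_size = as.integer(grid_size), pixel_spacing = pixel_spacing,
                 center = center, endo_radius = endo_radius,
                 epi_radius = epi_radius, reference_angle = reference_angle,
                 contour_offset = contour_offset, s0 = s0,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 blood_signal = blood_signal),
            class = "phantom_geometry")
}

#' Build AHA 16-segment pixel masks for three short-axis slices
#'
#' Partitions the eroded myocardial annulus of each slice into angular
#' sectors following the AHA convention: 6 sectors of 60 degrees on the
#' basal slice (segments 1-6), 6 on the mid-ventricular slice (7-12) and 4
#' sectors of 90 degrees on the apical slice (13-16), numbered
#' counterclockwise from the anterior right-ventricular insertion. Apical
#' sector boundaries are rotated by -15 degrees relative to segment 1's
#' origin so the four sector centres align with the anterior, septal,
#' inferior and lateral directions.
#'
#' @param geometry A [phantom_geometry()]. The same circular geometry is used
#'   for all three slices (idealized phantom; no long-axis taper).
#' @return An object of class `segment_masks`: a list with `labels`, an
#'   integer array `(grid, grid, 3)` with values 0 (outside) or 1-16, and
#'   `lookup`, a data frame mapping segment id to slice and sector index.
#' @export
build_segment_masks <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  g <- geometry
  n <- g$grid_size
  x <- (seq_len(n) - g$center[1]) * g$pixel_spacing
  y <- (g$center[2] - seq_len(n)) * g$pixel_spacing   # y axis up
  X <- matrix(x, n, n)
  Y <- matrix(y, n, n, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi) %% 360

  lo <- g$endo_radius + g$contour_offset
  hi <- g$epi_radius - g$contour_offset
  annulus <- r >= lo & r <= hi
  if (!any(annulus)) stop("eroded annulus contains no pixels")

  sector_labels <- function(origin, width, base_id) {
    sec <- floor(((theta - origin) %% 360) / width) + 1L
    lab <- matrix(0L, n, n)
    lab[annulus] <- base_id + sec[annulus] - 1L
    lab
  }
  labels <- array(0L, dim = c(n, n, 3))
  labels[, , 1] <- sector_labels(g$reference_angle, 60, 1L)    # basal
  labels[, , 2] <- sector_labels(g$reference_angle, 60, 7L)    # mid
  labels[, , 3] <- sector_labels(g$reference_angle - 15, 90, 13L)  # apical

  lookup <- data.frame(segment = 1:16,
                       aha_name = aha_segment_names(),
                       slice = as.character(aha_slice(1:16)),
                       sector = c(1:6, 1:6, 1:4))
  structure(list(labels = labels, lookup = lookup, geometry = g),
            class = "segment_masks")
}

#' Logical mask of one segment
#'
#' @param masks A `segment_masks` object.
#' @param segment Segment id in 1..16.
#' @return Logical matrix for the segment's slice.
#' @export
segment_mask <- function(masks, segment) {
  stopifnot(inherits(masks, "segment_masks"), segment %in% 1:16)
  slice <- c(1, 2, 3)[as.integer(aha_slice(segment))]
  masks$labels[, , slice] == segment
}

#' Bull's-eye report table of 16 segmental values
#'
#' Orders a 16-vector of per-segment values into the standard AHA report
#' rows ("1. basal anterior" ... "16. apical lateral").
#'
#' @param values Numeric vector of length 16, indexed by segment id.
#' @param value_name Column name for the values (default `"value"`).
#' @return Data frame with columns `segment`, `aha_name`, `slice` and the
#'   value column.
#' @examples
#' bullseye_table(reference_correction_factors("cvi42")$delta_r2star,
#'                value_name = "delta_r2star_hz")
#' @export
bullseye_table <- function(values, value_name = "value") {
  if (!is.numeric(values) || length(values) != 16) {
    stop("expected 16 segmental values")
  }
  out <- data.frame(segment = 1:16, aha_name = aha_segment_names(),
                    slice = as.character(aha_slice(1:16)))
  out[[value_name]] <- as.numeric(values)
  out
}

#' Polar bull's-eye plot of 16 segmental values
#'
#' Draws the standard three-ring polar display (apical innermost) with each
#' sector coloured by its value.
#'
#' @param values Numeric vector of length 16.
#' @param palette Colour ramp function (levels -> colours).
#' @param main Plot title.
#' @return Invisibly, the value range used for the colour scale.
#' @export
bullseye_plot <- function(values, palette = grDevices::hcl.colors, main = "") {
  stopifnot(is.numeric(values), length(values) == 16)
  rng <- range(values)
  cols <- palette(64)
  idx <- if (diff(rng) > 0) {
    pmin(64L, 1L + floor(63.999 * (values - rng[1]) / diff(rng)))
  } else rep(32L, 16)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  rings <- list(basal = c(0.7, 1), mid = c(0.4, 0.7), apical = c(0.15, 0.4))
  seg_ids <- list(basal = 1:6, mid = 7:12, apical = 13:16)
  origins <- c(basal = 60, mid = 60, apical = 45)
  for (ring in names(rings)) {
    ids <- seg_ids[[ring]]
    width <- 360 / length(ids)
    for (i in seq_along(ids)) {
      a0 <- origins[[ring]] + (i - 1) * width
      ang <- seq(a0, a0 + width, length.out = 30) * pi / 180
      r0 <- rings[[ring]][1]; r1 <- rings[[ring]][2]
      graphics::polygon(c(r0 * cos(ang), rev(r1 * cos(ang))),
                        c(r0 * sin(ang), rev(r1 * sin(ang))),
                        col = cols[idx[ids[i]]], border = "white")
      mid_a <- (a0 + width / 2) * pi / 180
      mid_r <- (r0 + r1) / 2
      graphics::text(mid_r * cos(mid_a), mid_r * sin(mid_a),
                     sprintf("%d", ids[i]), cex = 0.7)
    }
  }
  invisible(rng)
}
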