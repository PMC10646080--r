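# Per-organoid shape morphometry. Conventions:
#  - area = pixel count; equivalent diameter = sqrt(4A/pi)
#  - perimeter = arc length of the traced closed boundary polygon
#    (diagonal steps cost sqrt(2)); slightly biased, tolerances documented
#  - axes from the second-central-moment equivalent ellipse (regionprops
#    convention), eccentricity = sqrt(1 - (minor/major)^2)
#  - circularity = 4*pi*A/P^2, roundness = 4A/(pi*major^2): digitization
#    can push these slightly above 1; no clamp is applied
#  - solidity = A / convex-hull area (hull of boundary pixel centers,
#    ratio clamped at 1, so solid convex shapes score exactly 1)

# closed-boundary arc length with bias-corrected chain weights
# (0.948 axial, 1.340 diagonal — Vossepoel-Smeulders); the naive 1/sqrt(2)
# weighting overestimates smooth perimeters by ~5%, which would bias
# circularity well below 1 on discs
polygon_arc_length <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  nxt <- c(2:n, 1L)
  dr <- abs(pts[nxt, 1L] - pts[, 1L])
  dc <- abs(pts[nxt, 2L] - pts[, 2L])
  len <- sqrt(dr^2 + dc^2)                      # fallback: long jumps
  unit <- dr <= 1L & dc <= 1L
  len[unit & (dr + dc == 1L)] <- 0.948
  len[unit & (dr == 1L & dc == 1L)] <- 1.340
  sum(len)
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1L]; y <- pts[, 2L]
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

convex_hull_area <- function(boundary_pts) {
  # hull of boundary pixel centers; it slightly under-bounds the pixelated
  # region (a half-pixel rim), so the solidity ratio is clamped at 1 and
  # solid convex shapes score exactly 1
  h <- chull(boundary_pts)
  shoelace_area(boundary_pts[h, , drop = FALSE])
}

measure_one <- function(coords, boundary) {
  A <- nrow(coords)
  if (A == 0L) stop("empty region")
  P <- polygon_arc_length(boundary)
  r <- coords[, 1L]; c <- coords[, 2L]
  mu_r <- mean(r); mu_c <- mean(c)
  m20 <- mean((r - mu_r)^2); m02 <- mean((c - mu_c)^2)
  m11 <- mean((r - mu_r) * (c - mu_c))
  tr <- m20 + m02
  det <- m20 * m02 - m11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  lam1 <- tr / 2 + disc; lam2 <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(lam1); minor <- 4 * sqrt(lam2)
  ecc <- if (lam1 > 0) sqrt(max(1 - lam2 / lam1, 0)) else 0
  hull_area <- convex_hull_area(boundary)
  data.frame(
    area_px = A,
    equiv_diameter_px = sqrt(4 * A / pi),
    perimeter_px = P,
    major_axis_px = major,
    minor_axis_px = minor,
    eccentricity = ecc,
    circularity = if (P > 0) 4 * pi * A / P^2 else NA_real_,
    roundness = if (major > 0) 4 * A / (pi * major^2) else NA_real_,
    solidity = if (hull_area > 0) min(A / hull_area, 1) else NA_real_
  )
}

#' Measure one labeled organoid
#'
#' Computes the nine shape metrics of a single connected labeled region.
#'
#' @param contours a [labeled_contours] object.
#' @param id object label (1..n).
#' @return one-row data.frame of pixel-unit metrics.
#' @export
measure_object <- function(contours, id) {
  coords <- which(contours$labels == id, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("empty region: no pixels labeled ", id)
  measure_one(coords, contours$contours[[id]])
}

#' Measure all organoids in a labeled contour image
#'
#' @param contours a [labeled_contours] object (typically after
#'   [filter_objects()]).
#' @param image_id identifier recorded in the output rows.
#' @param um_per_px optional calibration; when present the micron-unit
#'   columns are filled via [convert_units()], otherwise they are NA.
#' @return data.frame in the canonical measurement schema (one row per
#'   organoid; see [write_measurements()]).
#' @export
measure_objects <- function(contours, image_id = "image", um_per_px = NULL) {
  n <- contours$n
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    m <- measure_object(contours, k)
    m <- cbind(data.frame(image_id = image_id, object_id = k), m)
    rows[[k]] <- m
  }
  df <- if (n > 0L) do.call(rbind, rows) else
    data.frame(image_id = character(0), object_id = integer(0),
               area_px = numeric(0), equiv_diameter_px = numeric(0),
               perimeter_px = numeric(0), major_axis_px = numeric(0),
               minor_axis_px = numeric(0), eccentricity = numeric(0),
               circularity = numeric(0), roundness = numeric(0),
               solidity = numeric(0))
  convert_units(df, um_per_px)
}

#' Convert pixel measurements to microns
#'
#' Lengths scale by \code{um_per_px}, areas by its square; dimensionless
#' metrics are untouched. With \code{um_per_px = NULL} the micron columns
#' are NA.
#'
#' @param measurements data.frame with pixel-unit columns (from
#'   [measure_objects()]).
#' @param um_per_px positive calibration, or NULL.
#' @return the data.frame with \code{*_um}/\code{*_um2} columns filled, in
#'   the canonical column order.
#' @export
convert_units <- function(measurements, um_per_px = NULL) {
  df <- measurements
  if (!is.null(um_per_px)) {
    if (!is.numeric(um_per_px) || um_per_px <= 0)
      stop("um_per_px must be > 0")
    r <- um_per_px
    df$area_um2 <- df$area_px * r^2
    df$equiv_diameter_um <- df$equiv_diameter_px * r
    df$perimeter_um <- df$perimeter_px * r
    df$major_axis_um <- df$major_axis_px * r
    df$minor_axis_um <- df$minor_axis_px * r
  } else {
    for (col in c("area_um2", "equiv_diameter_um", "perimeter_um",
                  "major_axis_um", "minor_axis_um"))
      df[[col]] <- rep(NA_real_, nrow(df))
  }
  df[, MEASUREMENT_COLUMNS[MEASUREMENT_COLUMNS %in% names(df)]]
}

#' Aggregate per-organoid measurements into per-image parameters
#'
#' Produces the culture-condition parameters: organoid count, total
#' projected area, total perimeter, and mean eccentricity. For an empty
#' image the totals are 0 and the mean eccentricity is NA (undefined).
#'
#' @param records data.frame of measurements from one image (possibly
#'   zero rows).
#' @param image_id identifier for the summary row (defaults to the one in
#'   \code{records} when unique).
#' @return one-row data.frame: image_id, count, total_area_px,
#'   total_area_um2, total_perimeter_px, total_perimeter_um,
#'   mean_eccentricity.
#' @export
summarize_image <- function(records, image_id = NULL) {
  if (is.null(image_id))
    image_id <- if (nrow(records) > 0L) unique(records$image_id)[1L] else "image"
  n <- nrow(records)
  data.frame(
    image_id = image_id,
    count = n,
    total_area_px = if (n) sum(records$area_px) else 0,
    total_area_um2 = if (n) sum(records$area_um2) else 0,
    total_perimeter_px = if (n) sum(records$perimeter_px) else 0,
    total_perimeter_um = if (n) sum(records$perimeter_um) else 0,
    mean_eccentricity = if (n) mean(records$eccentricity) else NA_real_
  )
}
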