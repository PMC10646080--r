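#' @importFrom stats rnorm runif rlnorm sd var cor cor.test lm coef median pt qnorm setNames
#' @importFrom utils write.csv read.csv head tail
#' @importFrom grDevices chull
NULL

MEASUREMENT_COLUMNS <- c(
  "image_id", "object_id",
  "area_px", "area_um2",
  "equiv_diameter_px", "equiv_diameter_um",
  "perimeter_px", "perimeter_um",
  "major_axis_px", "major_axis_um",
  "minor_axis_px", "minor_axis_um",
  "eccentricity", "circularity", "roundness", "solidity"
)

#' Brightfield organoid image
#'
#' Container for a single 2-D brightfield frame: an 8-bit grayscale pixel
#' grid plus optional micron calibration and acquisition metadata.
#'
#' @param pixels numeric matrix of intensities in \code{[0, 255]}, rows are
#'   image rows.
#' @param um_per_px optional positive micron-per-pixel calibration.
#' @param sample,day,well optional acquisition metadata (sample id string,
#'   non-negative integer day, well id string).
#' @return an object of class \code{organoid_image}.
#' @export
organoid_image <- function(pixels, um_per_px = NULL,
                           sample = NULL, day = NULL, well = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height and width >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  if (!is.null(um_per_px)) {
    if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0)
      stop("um_per_px must be a single positive number")
  }
  if (!is.null(day) && (day < 0 || day != round(day)))
    stop("day must be a non-negative integer")
  structure(
    list(pixels = pixels, um_per_px = um_per_px,
         meta = list(sample = sample, day = day, well = well)),
    class = "organoid_image"
  )
}

#' @export
print.organoid_image <- function(x, ...) {
  cat(sprintf("<organoid_image> %d x %d px", nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$um_per_px)) cat(sprintf(", %.4g um/px", x$um_per_px))
  m <- x$meta
  if (!is.null(m$sample)) cat(sprintf(", sample %s", m$sample))
  if (!is.null(m$day)) cat(sprintf(", day %d", m$day))
  cat("\n")
  invisible(x)
}

# decode a file into a row-major numeric array in [0,1]
decode_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected JPG/PNG/TIFF)")
  )
  if (length(arr) == 0L) stop("empty image: ", path)
  arr
}

# ITU-R BT.601 luma; idempotent on single-channel input
to_luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc == 1L) return(arr[, , 1L])
    if (nc >= 3L)
      return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
    if (nc == 2L) return(arr[, , 1L])  # gray + alpha
  }
  stop("cannot interpret image array with dims ",
       paste(dim(arr), collapse = "x"))
}

#' Read a brightfield image
#'
#' Decodes an 8-bit JPG/PNG/TIFF file. RGB input is collapsed to a single
#' channel by luminance weighting (BT.601); an alpha channel is dropped.
#'
#' @param path image file path.
#' @param um_per_px optional positive micron-per-pixel calibration attached
#'   to the result (calibration comes from configuration, not from the
#'   burned-in scale bar).
#' @param sample,day,well optional metadata, as in [organoid_image()].
#' @return an [organoid_image()].
#' @export
read_image <- function(path, um_per_px = NULL,
                       sample = NULL, day = NULL, well = NULL) {
  arr <- decode_raster(path)
  px <- round(to_luminance(arr) * 255)
  px[px < 0] <- 0; px[px > 255] <- 255
  organoid_image(px, um_per_px = um_per_px,
                 sample = sample, day = day, well = well)
}

#' Write a grayscale image
#'
#' PNG and TIFF are lossless (bit-exact round trip for 8-bit data);
#' JPG is lossy.
#'
#' @param image an [organoid_image()] or a numeric matrix in \code{[0,255]}.
#' @param path output path; format chosen from the extension.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "organoid_image")) image$pixels else as.matrix(image)
  v <- px / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, target = path),
    jpg = ,
    jpeg = jpeg::writeJPEG(v, target = path, quality = 0.95),
    tif = ,
    tiff = tiff::writeTIFF(v, where = path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Read a binary mask
#'
#' Masks use the 0/255 PNG dialect: background 0, foreground 255. A file
#' holding more than two distinct values is rejected.
#'
#' @param path PNG file path.
#' @return logical matrix; \code{TRUE} = foreground (organoid).
#' @export
read_mask <- function(path) {
  arr <- decode_raster(path)
  arr <- to_luminance(arr)
  vals <- sort(unique(as.vector(arr)))
  if (length(vals) > 2L)
    stop("not a binary mask: ", path, " holds ", length(vals),
         " distinct values")
  arr > 0
}

#' Write a binary mask
#'
#' @param mask logical matrix (\code{TRUE} = foreground).
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                target = path)
  invisible(path)
}

#' Write per-organoid measurements to CSV
#'
#' One row per organoid with the fixed column order
#' \code{image_id, object_id}, then the nine shape metrics in pixel and
#' micron units (micron columns are \code{NA} when uncalibrated).
#'
#' @param records a data.frame of measurements (from
#'   [measure_objects()]), or a list of such data.frames sharing one schema.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (length(records)) {
    schemas <- lapply(records, names)
    if (!all(vapply(schemas, identical, logical(1), y = schemas[[1L]])))
      stop("measurement records do not share a schema")
    df <- do.call(rbind, records)
  } else {
    df <- NULL
  }
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(
      setNames(rep(list(numeric(0)), length(MEASUREMENT_COLUMNS)),
               MEASUREMENT_COLUMNS))
  } else {
    missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
    if (length(missing_cols))
      stop("records lack required columns: ",
           paste(missing_cols, collapse = ", "))
    df <- df[, MEASUREMENT_COLUMNS]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#' @param path CSV path.
#' @return data.frame with the canonical measurement columns.
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# 3x5 bitmap digits for overlay annotation
.digit_font <- local({
  rows <- list(
    `0` = c("111","101","101","101","111"),
    `1` = c("010","110","010","010","111"),
    `2` = c("111","001","111","100","111"),
    `3` = c("111","001","111","001","111"),
    `4` = c("101","101","111","001","001"),
    `5` = c("111","100","111","001","111"),
    `6` = c("111","100","111","101","111"),
    `7` = c("111","001","001","001","001"),
    `8` = c("111","101","111","101","111"),
    `9` = c("111","101","111","001","111")
  )
  lapply(rows, function(r)
    do.call(rbind, lapply(strsplit(r, ""), function(s) as.integer(s) == 1L)))
})

# stamp integer `id` (white) centered at (row, col); scale in px per font px
draw_number <- function(canvas, id, row, col, scale = 2L) {
  digits <- strsplit(as.character(id), "")[[1L]]
  gw <- 3L * scale; gh <- 5L * scale; gap <- scale
  total_w <- length(digits) * gw + (length(digits) - 1L) * gap
  r0 <- round(row - gh / 2); c0 <- round(col - total_w / 2)
  for (k in seq_along(digits)) {
    glyph <- .digit_font[[digits[k]]]
    big <- glyph[rep(seq_len(5L), each = scale), rep(seq_len(3L), each = scale)]
    rr <- r0 + seq_len(gh) - 1L
    cc <- c0 + (k - 1L) * (gw + gap) + seq_len(gw) - 1L
    ok_r <- rr >= 1L & rr <= nrow(canvas)
    ok_c <- cc >= 1L & cc <= ncol(canvas)
    sub <- canvas[rr[ok_r], cc[ok_c], drop = FALSE]
    sub[big[ok_r, ok_c, drop = FALSE]] <- 255
    canvas[rr[ok_r], cc[ok_c]] <- sub
  }
  canvas
}

#' Render a numbered contour overlay
#'
#' Draws each object's boundary in white and stamps its integer ID at the
#' region centroid, either on a black background (the final contour-image
#' convention) or over the source image.
#'
#' @param image the source [organoid_image()] (used for shape, and as the
#'   backdrop when \code{on_source = TRUE}).
#' @param contours a [labeled_contours] object derived from an image of the
#'   same shape.
#' @param path output PNG path.
#' @param on_source draw over the source image instead of black.
#' @return \code{path}, invisibly.
#' @export
render_overlay <- function(image, contours, path, on_source = FALSE) {
  px <- if (inherits(image, "organoid_image")) image$pixels else as.matrix(image)
  if (!identical(dim(px), dim(contours$labels)))
    stop("contours were derived from an image of different shape")
  canvas <- if (on_source) px else matrix(0, nrow(px), ncol(px))
  for (k in seq_len(contours$n)) {
    b <- contours$contours[[k]]
    canvas[cbind(b[, 1L], b[, 2L])] <- 255
  }
  cen <- contour_centroids(contours)
  for (k in seq_len(contours$n))
    canvas <- draw_number(canvas, k, cen[k, 1L], cen[k, 2L])
  write_image(canvas, path)
  invisible(path)
}

#' Region centroids of labeled contours
#' @param contours a [labeled_contours] object.
#' @return matrix with one (row, col) centroid per object.
#' @export
contour_centroids <- function(contours) {
  n <- contours$n
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("row", "col")))
  if (n == 0L) return(out)
  idx <- which(contours$labels > 0L, arr.ind = TRUE)
  lab <- contours$labels[idx]
  out[, 1L] <- tapply(idx[, 1L], lab, mean)[as.character(seq_len(n))]
  out[, 2L] <- tapply(idx[, 2L], lab, mean)[as.character(seq_len(n))]
  out
}
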