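# Post-processing: raw binary segmentation -> cleaned, labeled contours.
# EBImage supplies the morphological kernels and hole filling; connected
# components are 8-connected (EBImage's 4-connected labels are merged
# across diagonal adjacencies), labels ascend in raster order of each
# component's topmost-then-leftmost pixel.

mask_to_eb <- function(mask) EBImage::Image(t(mask) * 1)
eb_to_matrix <- function(eb) t(EBImage::imageData(eb))

# 3x3 elliptical (cross-shaped) structuring element
STREL3 <- matrix(c(0, 1, 0,
                   1, 1, 1,
                   0, 1, 0), 3L, 3L)

# 8-connected labeling: fast 4-connected bwlabel, then union-find merge of
# labels that touch diagonally
label8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- eb_to_matrix(EBImage::bwlabel(mask_to_eb(mask)))
  storage.mode(lab) <- "integer"
  nl <- max(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  H <- nrow(lab); W <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    unique(cbind(a[sel], b[sel]))
  }
  prs <- rbind(
    diag_pairs(lab[-H, -W], lab[-1L, -1L]),   # down-right
    diag_pairs(lab[-H, -1L], lab[-1L, -W])    # down-left
  )
  if (nrow(prs)) {
    for (r in seq_len(nrow(prs))) {
      ra <- find(prs[r, 1L]); rb <- find(prs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nl), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  relabel_raster_order(lab)
}

# renumber labels 1..N ascending by first pixel in row-major raster order
relabel_raster_order <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  W <- ncol(lab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  key <- (idx[, 1L] - 1L) * W + (idx[, 2L] - 1L)   # row-major scan position
  first <- tapply(key, lab[idx], min)
  ord <- ids[order(first[as.character(ids)])]
  map <- integer(max(ids)); map[ord] <- seq_along(ord)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Clean a raw segmentation mask
#'
#' Applies, in order: (a) morphological opening then closing with a 3x3
#' elliptical structuring element, repeated \code{iterations} times;
#' (b) filling of all background holes fully enclosed by foreground;
#' (c) removal of connected components smaller than \code{min_area_px}.
#' The result has no enclosed holes and no undersized component, and the
#' operation is idempotent at fixed parameters.
#'
#' @param mask logical matrix (raw thresholded prediction).
#' @param iterations opening/closing repetitions.
#' @param min_area_px minimum component area kept, in pixels (a noise
#'   threshold, distinct from the biological size filter of
#'   [filter_objects()]).
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, iterations = 2L, min_area_px = 50L) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(mask & FALSE)
  eb <- mask_to_eb(mask)
  for (i in seq_len(iterations)) {
    eb <- EBImage::opening(eb, STREL3)
    eb <- EBImage::closing(eb, STREL3)
  }
  eb <- EBImage::fillHull(eb)
  out <- eb_to_matrix(eb) > 0
  if (min_area_px > 0L && any(out)) {
    lab <- label8(out)
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area_px)
    if (length(drop)) out[lab %in% drop] <- FALSE
  }
  out
}

#' Labeled organoid contours
#'
#' Constructor for the final contour representation: an integer label
#' image (0 = background, k = object k, labels consecutive from 1 in
#' raster order) plus each object's traced closed boundary as ordered
#' (row, col) pixel coordinates (1-based).
#'
#' @param labels integer label matrix.
#' @param contours list of boundary coordinate matrices, one per label.
#' @return an object of class \code{labeled_contours}.
#' @export
labeled_contours <- function(labels, contours) {
  n <- max(0L, max(labels))
  if (length(contours) != n) stop("one contour per label required")
  structure(list(labels = labels, contours = contours, n = n),
            class = "labeled_contours")
}

#' @export
print.labeled_contours <- function(x, ...) {
  cat(sprintf("<labeled_contours> %d object(s) in %d x %d label image\n",
              x$n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Label connected components and trace their contours
#'
#' 8-connected components of a cleaned mask are numbered in ascending
#' (raster) order and each boundary is traced as a closed polygon.
#'
#' @param mask cleaned logical matrix (see [clean_mask()]).
#' @return a [labeled_contours] object.
#' @export
label_contours <- function(mask) {
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) return(labeled_contours(lab, list()))
  oc <- EBImage::ocontour(EBImage::Image(t(lab)))
  contours <- vector("list", n)
  for (k in seq_len(n)) {
    pts <- oc[[k]]
    # EBImage coordinates are 0-based (x = our column, y = our row)
    contours[[k]] <- cbind(row = pts[, 2L] + 1L, col = pts[, 1L] + 1L)
  }
  labeled_contours(lab, contours)
}

object_areas <- function(lc) {
  if (lc$n == 0L) return(integer(0))
  tabulate(lc$labels[lc$labels > 0L], nbins = lc$n)
}

object_touches_border <- function(lc) {
  if (lc$n == 0L) return(logical(0))
  H <- nrow(lc$labels); W <- ncol(lc$labels)
  edge <- unique(c(lc$labels[1L, ], lc$labels[H, ],
                   lc$labels[, 1L], lc$labels[, W]))
  seq_len(lc$n) %in% edge[edge > 0L]
}

#' Select actual organoids
#'
#' Drops objects that touch any image border and objects whose equivalent
#' diameter, in microns, is below \code{min_diameter_um} — the selection
#' rule that separates actual organoids from cropped or undersized
#' detections. Survivors are relabeled 1..M preserving ascending order.
#'
#' @param contours a [labeled_contours] object.
#' @param um_per_px micron-per-pixel calibration; required when
#'   \code{min_diameter_um > 0}.
#' @param min_diameter_um minimum equivalent diameter in microns
#'   (default 40).
#' @param exclude_border drop border-touching objects.
#' @return a filtered [labeled_contours] object.
#' @export
filter_objects <- function(contours, um_per_px = NULL, min_diameter_um = 40,
                           exclude_border = TRUE) {
  lc <- contours
  if (lc$n == 0L) return(lc)
  keep <- rep(TRUE, lc$n)
  if (min_diameter_um > 0) {
    if (is.null(um_per_px))
      stop("um_per_px calibration required for a micron size threshold")
    areas <- object_areas(lc)
    d_um <- sqrt(4 * areas / pi) * um_per_px
    keep <- keep & d_um >= min_diameter_um
  }
  if (exclude_border) keep <- keep & !object_touches_border(lc)
  old_ids <- which(keep)
  map <- integer(lc$n); map[old_ids] <- seq_along(old_ids)
  labels <- lc$labels
  labels[labels > 0L] <- map[labels[labels > 0L]]
  labeled_contours(labels, lc$contours[old_ids])
}
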