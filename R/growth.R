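# Growth-curve analytics: Day-1-relative series, parameter/viability
# correlation, and the subculture time point flag.

#' Normalize a per-day series to its Day-1 value
#'
#' Each value is divided by the earliest day's value, so the series starts
#' at exactly 1; input is re-sorted by day first.
#'
#' @param values numeric per-day values.
#' @param days matching day numbers (default \code{1..length(values)}).
#' @return data.frame: day, value, relative (sorted by day).
#' @export
relative_series <- function(values, days = seq_along(values)) {
  if (length(values) != length(days)) stop("values and days differ in length")
  if (anyDuplicated(days)) stop("duplicate days")
  o <- order(days)
  values <- values[o]; days <- days[o]
  ref <- values[1L]
  if (is.na(ref) || ref <= 0) stop("Day-1 value missing or non-positive")
  data.frame(day = days, value = values, relative = values / ref)
}

#' Correlate image-derived parameters with viability readouts
#'
#' For each per-well image parameter (every numeric column of
#' \code{summaries} other than identifiers), computes the Pearson
#' correlation against the viability values and ranks the parameters by r.
#'
#' @param summaries data.frame with one row per well/image, containing a
#'   \code{well} column and numeric parameter columns.
#' @param viability numeric vector aligned with the rows of
#'   \code{summaries}, or a data.frame with \code{well} and
#'   \code{viability} columns to be joined.
#' @return data.frame: parameter, r, p, rank (rank 1 = largest r).
#' @export
correlate_parameters <- function(summaries, viability) {
  if (is.data.frame(viability)) {
    if (!anyDuplicated(viability$well)) {
      m <- match(summaries$well, viability$well)
      if (anyNA(m)) stop("viability values missing for some wells")
      v <- viability$viability[m]
    } else if (nrow(viability) == nrow(summaries)) {
      v <- viability$viability   # replicate wells imaged repeatedly: row-aligned
    } else {
      stop("cannot align viability values with summaries")
    }
  } else {
    if (length(viability) != nrow(summaries))
      stop("one viability value per summary row required")
    v <- viability
  }
  if (length(v) < 3L) stop("need at least 3 wells")
  skip <- c("well", "image_id", "day", "dilution_level", "viability")
  params <- setdiff(names(summaries)[vapply(summaries, is.numeric,
                                            logical(1))], skip)
  if (!length(params)) stop("no numeric parameter columns found")
  res <- do.call(rbind, lapply(params, function(pname) {
    pr <- pearson(summaries[[pname]], v)
    data.frame(parameter = pname, r = pr$r, p = pr$p)
  }))
  res <- res[order(-res$r), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Flag the subculture time point
#'
#' The subculture time point is the first day whose day-over-day relative
#' growth falls below \code{slowdown_fraction} — the operational form of
#' "growth has slowed down". Returns \code{NA} when growth never slows
#' (not reached).
#'
#' @param values per-day values (raw or Day-1-relative; the rule is
#'   scale-invariant).
#' @param days matching day numbers, strictly increasing.
#' @param slowdown_fraction relative growth threshold (default 0.10).
#' @return the flagged day, or \code{NA_integer_} if not reached.
#' @export
subculture_timepoint <- function(values, days = seq_along(values),
                                 slowdown_fraction = 0.10) {
  if (length(values) != length(days)) stop("values and days differ in length")
  if (length(values) < 3L) stop("need at least 3 days")
  if (anyDuplicated(days)) stop("duplicate days")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be increasing")
  growth <- diff(values) / head(values, -1L)
  hit <- which(growth < slowdown_fraction)
  if (!length(hit)) return(NA_integer_)
  as.integer(days[hit[1L] + 1L])
}

#' Build replicate-normalized growth curves
#'
#' Normalizes each replicate's series to its own Day-1 value, then reports
#' mean and SD of the relative values across replicates, with the
#' subculture flag from the mean curve.
#'
#' @param records data.frame with columns day, well (replicate) and one or
#'   more parameter columns.
#' @param parameter name of the parameter column to curve.
#' @param slowdown_fraction passed to [subculture_timepoint()].
#' @return data.frame: day, mean_relative, sd_relative, flag_subculture
#'   (TRUE on the flagged day).
#' @export
growth_curve <- function(records, parameter = "total_area_px",
                         slowdown_fraction = 0.10) {
  if (!parameter %in% names(records)) stop("no column ", parameter)
  wells <- unique(records$well)
  rel <- lapply(wells, function(w) {
    sub <- records[records$well == w, ]
    relative_series(sub[[parameter]], sub$day)
  })
  days <- sort(unique(records$day))
  relmat <- vapply(rel, function(r) r$relative[match(days, r$day)],
                   numeric(length(days)))
  relmat <- matrix(relmat, nrow = length(days))
  mean_rel <- rowMeans(relmat)
  sd_rel <- apply(relmat, 1L, sd)
  flag_day <- subculture_timepoint(mean_rel, days, slowdown_fraction)
  data.frame(day = days, mean_relative = mean_rel, sd_relative = sd_rel,
             flag_subculture = !is.na(flag_day) & days == flag_day)
}
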