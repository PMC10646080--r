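# Segmentation and detection scoring plus the agreement statistics used to
# benchmark the pipeline against manual counts and viability assays.

#' Dice similarity coefficient
#'
#' Pixel-overlap agreement \eqn{2|P \cap G| / (|P| + |G|)}. Two empty
#' masks agree vacuously (DSC = 1).
#'
#' @param pred,gt logical matrices of equal shape.
#' @return scalar in \code{[0, 1]}.
#' @export
dice <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch")
  s <- sum(pred) + sum(gt)
  if (s == 0) return(1)
  2 * sum(pred & gt) / s
}

# list of linear-index pixel sets per object
object_pixel_sets <- function(x) {
  if (inherits(x, "labeled_contours")) {
    lab <- x$labels
    if (x$n == 0L) return(list())
    return(split(which(lab > 0L), lab[lab > 0L]))
  }
  if (is.list(x)) return(lapply(x, function(m) which(as.vector(m))))
  stop("cannot interpret object set")
}

#' Ground-truth detection instances from a synthetic scene
#'
#' Rasterizes every rendered entity of a [generate_scene()] result into a
#' detection ground-truth set: in-focus organoids are positive instances,
#' out-of-focus distractors are negative instances (objects that a correct
#' detector must NOT report).
#'
#' @param scene a [generate_scene()] result.
#' @return list: \code{pixels} (per-object linear-index sets) and
#'   \code{negative} (logical vector).
#' @export
truth_instances <- function(scene) {
  obj <- scene$objects
  shape <- dim(scene$mask)
  px <- lapply(seq_len(nrow(obj)), function(i) {
    which(as.vector(rasterize_ellipse(
      c(obj$center_row[i], obj$center_col[i]), c(obj$a[i], obj$b[i]),
      obj$orientation[i], shape)))
  })
  list(pixels = px, negative = obj$is_distractor)
}

#' IoU-matched detection confusion matrix
#'
#' Predictions are matched one-to-one to ground-truth instances greedily
#' by descending pairwise IoU; a pair counts as a match at
#' \code{IoU >= iou_threshold}. Matched positives are TP, unmatched
#' positives FN. Predictions not matched to a positive (stray, or matching
#' a negative/distractor instance) are FP, and negatives left unmatched —
#' correctly ignored distractors — are TN. Rates with a zero denominator
#' are returned as NA.
#'
#' @param pred a [labeled_contours] object or list of logical masks.
#' @param truth a [truth_instances()] result (or any list with
#'   \code{pixels} and \code{negative}).
#' @param iou_threshold match threshold in \code{(0, 1]}.
#' @return a \code{detection_report}: counts TP/FP/FN/TN, sensitivity,
#'   specificity, accuracy, and the threshold used.
#' @export
match_objects <- function(pred, truth, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  P <- object_pixel_sets(pred)
  G <- truth$pixels
  neg <- truth$negative
  np <- length(P); ng <- length(G)
  iou <- matrix(0, max(np, 1L), max(ng, 1L))
  if (np && ng) {
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      inter <- sum(P[[i]] %in% G[[j]])
      if (inter > 0)
        iou[i, j] <- inter / (length(P[[i]]) + length(G[[j]]) - inter)
    }
  }
  matched_p <- logical(np); matched_g <- logical(ng)
  if (np && ng) {
    repeat {
      m <- which(iou == max(iou), arr.ind = TRUE)[1L, , drop = TRUE]
      if (iou[m[1L], m[2L]] < iou_threshold) break
      matched_p[m[1L]] <- TRUE; matched_g[m[2L]] <- TRUE
      iou[m[1L], ] <- -1; iou[, m[2L]] <- -1
      if (all(matched_p) || all(matched_g)) break
    }
  }
  tp <- sum(matched_g & !neg)
  fn <- sum(!matched_g & !neg)
  tn <- sum(!matched_g & neg)
  fp <- np - tp                      # stray or distractor-matching preds
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = rate(tp + tn, tp + tn + fp + fn),
    iou_threshold = iou_threshold,
    n_pred = np, n_true = sum(!neg), n_negative = sum(neg)
  ), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> TP %d FP %d FN %d TN %d | sens %.3f spec %.3f acc %.3f (IoU >= %.2f)\n",
    x$TP, x$FP, x$FN, x$TN, x$sensitivity, x$specificity, x$accuracy,
    x$iou_threshold))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with
#' Lin's original n-denominator moments; the 95% CI is built on the Fisher
#' z-transform with Lin's asymptotic standard error.
#'
#' @param x,y numeric vectors of equal length, \code{n >= 3}.
#' @param conf confidence level.
#' @return list: \code{estimate}, \code{ci} (lower, upper), \code{n}. When
#'   both inputs are constant and equal the estimate is undefined:
#'   \code{estimate} is NA and \code{undefined} is TRUE.
#' @export
ccc <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                undefined = TRUE))
  est <- 2 * sxy / denom
  ci_out <- c(NA_real_, NA_real_)
  if (sx2 > 0 && sy2 > 0 && abs(est) < 1) {
    r <- sxy / sqrt(sx2 * sy2)
    if (r != 0) {
      u <- (mx - my) / (sx2 * sy2)^0.25
      C <- est
      sz2 <- ((1 - r^2) * C^2 / ((1 - C^2) * r^2) +
              4 * C^3 * (1 - C) * u^2 / (r * (1 - C^2)^2) -
              2 * C^4 * u^4 / (r^2 * (1 - C^2)^2)) / (n - 2)
      if (is.finite(sz2) && sz2 >= 0) {
        z <- atanh(C)
        hw <- qnorm(1 - (1 - conf) / 2) * sqrt(sz2)
        ci_out <- tanh(c(z - hw, z + hw))
      }
    }
  }
  list(estimate = est, ci = ci_out, n = n, undefined = FALSE)
}

#' Pearson correlation with two-sided P
#'
#' Sample correlation; P from the t statistic
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y numeric vectors, \code{n >= 3}.
#' @return list: \code{r}, \code{p}, \code{n}; zero-variance input gives
#'   \code{r = NA} with \code{undefined = TRUE}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, undefined = FALSE)
}

#' Ordinary least squares fit with R-squared
#'
#' @param x,y numeric vectors, \code{n >= 3}; \code{x} must vary.
#' @return list: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p} (slope two-sided P).
#' @export
linregress_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (sd(x) == 0) stop("x is constant; no regression possible")
  if (sd(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0, p = NA_real_))
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # noiseless fits are legitimate here
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = s$r.squared, p = s$coefficients[2L, 4L])
}

#' Score a set of predictions against ground truth
#'
#' Computes the dice coefficient of every raw prediction and of its
#' post-processed version ([clean_mask()]), and their separate means —
#' noise removal can trade a little DSC for cleaner object analysis, so
#' both are reported.
#'
#' @param pred_masks,gt_masks equal-length lists of logical matrices.
#' @param iterations,min_area_px post-processing parameters.
#' @return list: \code{per_image} (data.frame image, dsc_raw, dsc_post),
#'   \code{mean_raw}, \code{mean_post}.
#' @export
evaluate_set <- function(pred_masks, gt_masks, iterations = 2L,
                         min_area_px = 50L) {
  if (length(pred_masks) != length(gt_masks))
    stop("prediction and ground-truth lists differ in length")
  n <- length(pred_masks)
  raw <- post <- numeric(n)
  for (i in seq_len(n)) {
    raw[i] <- dice(pred_masks[[i]], gt_masks[[i]])
    post[i] <- dice(clean_mask(pred_masks[[i]], iterations, min_area_px),
                    gt_masks[[i]])
  }
  list(per_image = data.frame(image = seq_len(n), dsc_raw = raw,
                              dsc_post = post),
       mean_raw = mean(raw), mean_post = mean(post))
}
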