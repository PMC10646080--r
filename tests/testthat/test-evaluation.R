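test_that("dice coefficient matches closed forms and is symmetric", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  half <- matrix(FALSE, 4, 4); half[1:2, 1] <- TRUE; half[3:4, 4] <- TRUE
  expect_equal(dice(a, half), 0.5)   # |P|=|G|=4, overlap 2
  e <- matrix(FALSE, 3, 3)
  expect_equal(dice(e, e), 1)        # vacuous agreement
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, matrix(FALSE, 3, 3)), "shape")
  set.seed(12)
  for (i in 1:10) {
    p <- matrix(runif(64) < 0.4, 8, 8); g <- matrix(runif(64) < 0.4, 8, 8)
    expect_equal(dice(p, g), brute_dice(p, g), tolerance = 1e-15)
  }
})

test_that("detection matching reproduces the confusion-matrix oracle", {
  shape <- c(120, 160)
  mk <- function(r, c, rad) rasterize_ellipse(c(r, c), c(rad, rad), 0, shape)
  # 4 true organoids, 3 distractors
  truths <- list(mk(20, 20, 10), mk(20, 120, 10), mk(90, 30, 12),
                 mk(90, 120, 10),                       # positives
                 mk(55, 70, 8), mk(20, 70, 8), mk(100, 75, 8))  # negatives
  truth <- list(pixels = lapply(truths, function(m) which(as.vector(m))),
                negative = c(rep(FALSE, 4), rep(TRUE, 3)))
  # 3 of 4 positives detected; 1 distractor falsely detected
  preds <- list(mk(20, 20, 10), mk(21, 120, 10), mk(89, 30, 12),
                mk(55, 70, 8))
  rep <- match_objects(preds, truth, iou_threshold = 0.5)
  expect_equal(rep$TP, 3L); expect_equal(rep$FN, 1L)
  expect_equal(rep$FP, 1L); expect_equal(rep$TN, 2L)
  expect_equal(rep$sensitivity, 0.75)
  expect_equal(rep$specificity, 2 / 3)
  expect_equal(rep$accuracy, 5 / 7)
  expect_equal(rep$TP + rep$FN, rep$n_true)

  # predictions identical to ground truth
  perfect <- match_objects(truths[1:4],
                           list(pixels = truth$pixels[1:4],
                                negative = rep(FALSE, 4)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$FP, 0L)
  expect_true(is.na(perfect$specificity))  # no negatives: undefined, flagged

  # zero predictions
  none <- match_objects(list(), truth)
  expect_equal(none$TP, 0L); expect_equal(none$FN, 4L)
  expect_equal(none$sensitivity, 0)

  expect_error(match_objects(preds, truth, iou_threshold = 0), "iou_threshold")
})

test_that("Lin's CCC matches hand computation and penalizes shifts", {
  x <- c(1, 2, 3)
  expect_equal(ccc(x, x)$estimate, 1)
  sh <- ccc(x, x + 2)
  expect_lt(sh$estimate, 1)
  expect_equal(pearson(x, x + 2)$r, 1)
  # hand evaluation of Lin's formula on (1,2,3) vs (1,2,4): 6/7
  expect_equal(ccc(x, c(1, 2, 4))$estimate, 6 / 7, tolerance = 1e-12)
  # degenerate: both constant and equal
  expect_true(ccc(c(2, 2, 2), c(2, 2, 2))$undefined)
  # CI brackets the estimate
  set.seed(3)
  xx <- rnorm(30); yy <- xx + rnorm(30, sd = 0.3)
  cc <- ccc(xx, yy)
  expect_true(cc$ci[1] < cc$estimate && cc$estimate < cc$ci[2])
  expect_error(ccc(1:2, 1:2), "n >= 3")
})

test_that("Pearson and OLS agree with brute-force formulas", {
  x <- c(1, 3, 5, 7)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  # constructed orthogonal pair
  y <- c(1, -1, -1, 1)
  expect_equal(pearson(x, y)$r, 0)
  expect_true(pearson(c(1, 1, 1), 1:3)$undefined)
  set.seed(9)
  xx <- rnorm(10); yy <- rnorm(10)
  expect_equal(pearson(xx, yy)$r, brute_pearson(xx, yy), tolerance = 1e-12)

  fit <- linregress_r2(x, 2 * x + 1)
  expect_equal(fit$slope, 2); expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(linregress_r2(x, rep(3, 4))$r_squared, 0)
  expect_error(linregress_r2(rep(1, 4), x), "constant")
  bf <- brute_ols(xx, yy)
  fit2 <- linregress_r2(xx, yy)
  expect_equal(fit2$slope, bf$slope, tolerance = 1e-12)
  expect_equal(fit2$r_squared, bf$r_squared, tolerance = 1e-12)
})

test_that("CCC magnitude never exceeds Pearson's and matches it when aligned", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(15); y <- rnorm(15) * runif(1, 0.5, 2) + runif(1, -2, 2)
    expect_lte(abs(ccc(x, y)$estimate), abs(pearson(x, y)$r) + 1e-12)
  }
  x <- rnorm(20); y <- x + rnorm(20)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x)  # match mean and variance
  expect_equal(ccc(x, y)$estimate, pearson(x, y)$r, tolerance = 1e-10)
})

test_that("evaluate_set reports raw and post-processed DSC", {
  g1 <- matrix(FALSE, 40, 40); g1[5:20, 5:20] <- TRUE
  g2 <- matrix(FALSE, 40, 40); g2[10:30, 10:30] <- TRUE
  perfect <- evaluate_set(list(g1, g2), list(g1, g2))
  expect_equal(perfect$mean_raw, 1)
  # mean of {1.0, 0.5}: half-overlapping second prediction
  p2 <- matrix(FALSE, 40, 40)
  ov <- floor(sum(g2) / 2)
  idx <- which(g2)[seq_len(ov)]
  p2[idx] <- TRUE
  p2[1:2, 35:39] <- TRUE  # pad |P| back up to |G|
  np <- sum(p2)
  expect_equal(dice(p2, g2), 2 * ov / (np + sum(g2)))
  res <- evaluate_set(list(g1, p2), list(g1, g2), min_area_px = 0L,
                      iterations = 0L)
  expect_equal(res$mean_raw, mean(c(1, dice(p2, g2))))
  expect_error(evaluate_set(list(g1), list(g1, g2)), "length")
})
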