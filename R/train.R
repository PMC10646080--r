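#' Training configuration
#'
#' Full-scale defaults: 512x512 random crops, batches of eight, stochastic
#' gradient descent at learning rate 0.001, and a compound dice +
#' cross-entropy loss with unit weights. The augmentation family is random
#' flipping, rotation, affine transformation and Gaussian blurring; all
#' magnitudes are configurable.
#'
#' @param crop square crop size for training patches.
#' @param batch minibatch size.
#' @param lr SGD learning rate.
#' @param momentum SGD momentum.
#' @param epochs training epochs.
#' @param flip_p per-axis flip probability.
#' @param rot_range rotation range in degrees (uniform in \code{±rot_range}).
#' @param scale_range affine scale factor range.
#' @param translate_frac max affine translation as a fraction of the side.
#' @param blur_sigma_range Gaussian blur sigma range (image only).
#' @param loss_weights weights of (cross-entropy, dice) terms.
#' @param seed RNG seed for cropping, augmentation and shuffling.
#' @return a \code{train_config} list.
#' @export
train_config <- function(crop = 512L, batch = 8L, lr = 0.001, momentum = 0.9,
                         epochs = 200L, flip_p = 0.5, rot_range = 180,
                         scale_range = c(0.9, 1.1), translate_frac = 0.1,
                         blur_sigma_range = c(0, 1.5),
                         loss_weights = c(1, 1), seed = 1L) {
  stopifnot(crop >= 1L, batch >= 1L, lr > 0, momentum >= 0, epochs >= 0L)
  structure(as.list(environment()), class = "train_config")
}

#' Soft dice loss
#'
#' \eqn{1 - (2\sum pg + \epsilon) / (\sum p + \sum g + \epsilon)} with
#' smoothing \eqn{\epsilon = 1}; lies in \code{[0, 1]}.
#'
#' @param prob probability map, values in \code{[0, 1]}.
#' @param gt ground-truth mask (logical or 0/1), same shape.
#' @return scalar loss.
#' @export
dice_loss <- function(prob, gt) {
  if (!identical(dim(prob), dim(gt))) stop("shape mismatch")
  g <- as.numeric(gt)
  p <- as.numeric(prob)
  1 - (2 * sum(p * g) + 1) / (sum(p) + sum(g) + 1)
}

CE_CLIP <- 1e-7

#' Binary cross-entropy loss
#'
#' Mean pixelwise binary cross-entropy; probabilities are clipped to
#' \code{(1e-7, 1 - 1e-7)} before the logarithm.
#'
#' @inheritParams dice_loss
#' @return scalar loss, non-negative.
#' @export
cross_entropy_loss <- function(prob, gt) {
  if (!identical(dim(prob), dim(gt))) stop("shape mismatch")
  g <- as.numeric(gt)
  p <- pmin(pmax(as.numeric(prob), CE_CLIP), 1 - CE_CLIP)
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

#' Compound segmentation loss
#'
#' The training objective: the sum of the cross-entropy and dice losses
#' (unit weights by default).
#'
#' @inheritParams dice_loss
#' @param weights numeric (cross-entropy weight, dice weight).
#' @return scalar loss.
#' @export
compound_loss <- function(prob, gt, weights = c(1, 1)) {
  weights[1L] * cross_entropy_loss(prob, gt) +
    weights[2L] * dice_loss(prob, gt)
}

#' Gradient of the compound loss with respect to the probability map
#'
#' Analytic gradient used by the trainer (and checkable against finite
#' differences).
#'
#' @inheritParams compound_loss
#' @return array of the same shape as \code{prob}.
#' @export
compound_loss_grad <- function(prob, gt, weights = c(1, 1)) {
  if (!identical(dim(prob), dim(gt))) stop("shape mismatch")
  g <- array(as.numeric(gt), dim(prob))
  p <- prob
  n <- length(p)
  pc <- pmin(pmax(p, CE_CLIP), 1 - CE_CLIP)
  dce <- (-g / pc + (1 - g) / (1 - pc)) / n
  dce[p < CE_CLIP | p > 1 - CE_CLIP] <- 0
  denom <- sum(p) + sum(g) + 1
  num <- 2 * sum(p * g) + 1
  ddice <- -(2 * g * denom - num) / denom^2
  weights[1L] * dce + weights[2L] * ddice
}

# bilinear (image) / nearest (mask) inverse-mapped affine warp about center
warp_pair <- function(img, mask, theta, scale, tr, tc) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy - tr
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - tc
  ct <- cos(-theta); st <- sin(-theta)
  sy <- (gy * ct - gx * st) / scale + cy
  sx <- (gy * st + gx * ct) / scale + cx
  # nearest for the mask
  ry <- round(sy); rx <- round(sx)
  inb <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
  new_mask <- matrix(FALSE, H, W)
  new_mask[inb] <- mask[cbind(ry[inb], rx[inb])]
  # bilinear for the image, edge-clamped
  y0 <- as.vector(pmin(pmax(floor(sy), 1), H))
  x0 <- as.vector(pmin(pmax(floor(sx), 1), W))
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(as.vector(sy) - y0, 0), 1)
  fx <- pmin(pmax(as.vector(sx) - x0, 0), 1)
  v <- img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
       img[cbind(y0, x1)] * (1 - fy) * fx +
       img[cbind(y1, x0)] * fy * (1 - fx) +
       img[cbind(y1, x1)] * fy * fx
  bg <- stats::median(img)
  out <- matrix(bg, H, W)
  keep <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  out[keep] <- v[as.vector(keep)]
  list(img = out, mask = new_mask)
}

#' Paired stochastic augmentation
#'
#' Applies the same random geometric transform (flips, rotation, affine
#' scale/translation) to an image and its mask — nearest-neighbour
#' resampling keeps the mask binary — and Gaussian blur to the image only.
#' Uses R's current RNG stream; seed upstream for reproducibility.
#'
#' @param image numeric matrix (intensities).
#' @param mask logical matrix, same shape.
#' @param config a [train_config()] supplying the magnitudes.
#' @return list \code{(image, mask)}.
#' @export
augment <- function(image, mask, config = train_config()) {
  if (!identical(dim(image), dim(mask))) stop("shape mismatch")
  img <- image
  if (config$flip_p > 0) {
    if (runif(1) < config$flip_p) { img <- img[, rev(seq_len(ncol(img)))]; mask <- mask[, rev(seq_len(ncol(mask)))] }
    if (runif(1) < config$flip_p) { img <- img[rev(seq_len(nrow(img))), ]; mask <- mask[rev(seq_len(nrow(mask))), ] }
  }
  theta <- if (config$rot_range > 0)
    runif(1, -config$rot_range, config$rot_range) * pi / 180 else 0
  scale <- if (diff(range(config$scale_range)) > 0 ||
               any(config$scale_range != 1))
    runif(1, config$scale_range[1L], config$scale_range[2L]) else 1
  tmax_r <- config$translate_frac * nrow(img)
  tmax_c <- config$translate_frac * ncol(img)
  tr <- if (tmax_r > 0) runif(1, -tmax_r, tmax_r) else 0
  tc <- if (tmax_c > 0) runif(1, -tmax_c, tmax_c) else 0
  if (theta != 0 || scale != 1 || tr != 0 || tc != 0) {
    wp <- warp_pair(img, mask, theta, scale, tr, tc)
    img <- wp$img; mask <- wp$mask
  }
  smax <- config$blur_sigma_range[2L]
  if (smax > 0) {
    sigma <- runif(1, config$blur_sigma_range[1L], smax)
    if (sigma > 0.05) img <- blur_matrix(img, sigma)
  }
  list(image = img, mask = mask)
}

# gradient trees ---------------------------------------------------------

# element-wise combine of two parameter trees; keyed by name so the two
# trees may list their leaves in different orders
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      if (is.null(a[[key]])) next
      out[[key]] <- tree_map2(f, a[[key]], b[[key]])
    }
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, function(e) if (is.null(e)) NULL else tree_zero(e))
  else a * 0
}

# conv par lists carry k/cin/cout integers; SGD touches only the arrays
strip_meta <- function(par) {
  if (is.list(par)) {
    keep <- setdiff(names(par), c("k", "cin", "cout"))
    out <- lapply(par[keep], strip_meta)
    out
  } else par
}

graft_meta <- function(new, orig) {
  if (is.list(orig)) {
    out <- orig
    for (nm in names(orig)) {
      if (nm %in% c("k", "cin", "cout")) next
      if (!is.null(orig[[nm]])) out[[nm]] <- graft_meta(new[[nm]], orig[[nm]])
    }
    out
  } else new
}

#' Train the segmentation network
#'
#' Per epoch: one random square crop per training image, stochastic
#' augmentation, minibatch SGD (momentum) on the compound loss; after each
#' epoch the mean dice coefficient of thresholded predictions on the
#' validation set is recorded, and the weights of the best-validation
#' epoch are returned.
#'
#' @param model an \code{msunet} from [build_model()].
#' @param train_set,val_set non-empty lists of \code{list(image, mask)}
#'   pairs (image: [organoid_image()] or matrix in \code{[0,255]}).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list: \code{model} (best-epoch weights) and \code{history}
#'   (data.frame: epoch, loss_total, loss_ce, loss_dice, val_dsc;
#'   plus \code{best_epoch} attribute).
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  verbose = FALSE) {
  if (!length(train_set) || !length(val_set)) stop("empty train/val set")
  get_px <- function(s)
    if (inherits(s$image, "organoid_image")) s$image$pixels else s$image
  dims <- vapply(train_set, function(s) dim(get_px(s)), integer(2))
  if (any(dims < config$crop)) stop("crop larger than training images")
  history <- data.frame(epoch = integer(0), loss_total = numeric(0),
                        loss_ce = numeric(0), loss_dice = numeric(0),
                        val_dsc = numeric(0))
  if (config$epochs == 0L) {
    attr(history, "best_epoch") <- NA_integer_
    return(list(model = model, history = history))
  }
  set.seed(config$seed)
  velocity <- tree_zero(strip_meta(model$params))
  best <- list(dsc = -Inf, params = model$params, epoch = NA_integer_)
  n <- length(train_set)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_ce <- ep_di <- 0; nb <- 0
    batch_grads <- NULL; batch_count <- 0L
    flush_batch <- function() {
      velocity <<- tree_map2(function(v, gr) config$momentum * v -
                               config$lr * gr / batch_count,
                             velocity, batch_grads)
      stripped <- tree_map2(`+`, strip_meta(model$params), velocity)
      model$params <<- graft_meta(stripped, model$params)
      batch_grads <<- NULL; batch_count <<- 0L
    }
    for (i in ord) {
      px <- get_px(train_set[[i]]); mk <- train_set[[i]]$mask
      H <- nrow(px); W <- ncol(px); cs <- config$crop
      r0 <- sample.int(H - cs + 1L, 1L); c0 <- sample.int(W - cs + 1L, 1L)
      ci <- px[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
      cm <- mk[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
      au <- augment(ci, cm, config)
      x <- au$image / 255
      fw <- model_forward(model, x, keep_cache = TRUE)
      prob <- sigmoid(fw$logits)
      gt <- array(as.numeric(au$mask), dim(prob))
      lce <- cross_entropy_loss(prob, gt)
      ldi <- dice_loss(prob, gt)
      ep_ce <- ep_ce + lce; ep_di <- ep_di + ldi; nb <- nb + 1
      dprob <- compound_loss_grad(prob, gt, config$loss_weights)
      dlogits <- dprob * prob * (1 - prob)
      grads <- model_backward(model, dlogits, fw$caches)
      grads <- strip_meta(grads)
      batch_grads <- if (is.null(batch_grads)) grads else
        tree_map2(`+`, batch_grads, grads)
      batch_count <- batch_count + 1L
      if (batch_count >= config$batch) flush_batch()
    }
    if (batch_count > 0L) flush_batch()
    val_dsc <- mean(vapply(val_set, function(s) {
      pm <- predict_mask(model, get_px(s))
      dice(pm$mask, s$mask)
    }, numeric(1)))
    history <- rbind(history, data.frame(
      epoch = ep, loss_total = (ep_ce + ep_di) / nb,
      loss_ce = ep_ce / nb, loss_dice = ep_di / nb, val_dsc = val_dsc))
    if (val_dsc > best$dsc)
      best <- list(dsc = val_dsc, params = model$params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f (ce %.4f dice %.4f)  val DSC %.4f",
                      ep, (ep_ce + ep_di) / nb, ep_ce / nb, ep_di / nb,
                      val_dsc))
  }
  model$params <- best$params
  attr(history, "best_epoch") <- best$epoch
  list(model = model, history = history)
}
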