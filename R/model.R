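#' Multi-scale residual U-Net configuration
#'
#' Each encoder/decoder block runs two parallel convolution branches — a
#' 3x3 and a 7x7 kernel — whose outputs are concatenated and fused by a
#' 1x1 convolution, with a residual shortcut (1x1-projected when the
#' channel counts differ). Downsampling is 2x2 max pooling, upsampling
#' nearest-neighbour followed by a 1x1 channel projection. The final layer
#' is a 1x1 convolution with a sigmoid, producing a per-pixel organoid
#' probability map.
#'
#' @param depth number of encoder levels (pooling steps), >= 1.
#' @param base_channels channels at the first level; doubled per level.
#' @param kernels the two parallel kernel sizes of every block.
#' @param in_channels input channels (1 for grayscale).
#' @param seed RNG seed for weight initialization.
#' @return a \code{model_config} list.
#' @export
model_config <- function(depth = 4L, base_channels = 32L,
                         kernels = c(3L, 7L), in_channels = 1L, seed = 1L) {
  stopifnot(depth >= 1L, base_channels >= 1L, in_channels >= 1L,
            length(kernels) == 2L, all(kernels %% 2L == 1L))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 kernels = as.integer(kernels),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "model_config")
}

block_init <- function(cin, cout, kernels) {
  par <- list(
    conv_a = conv_init(kernels[1L], cin, cout),
    norm_a = norm_init(cout),
    conv_b = conv_init(kernels[2L], cin, cout),
    norm_b = norm_init(cout),
    fuse = conv_init(1L, 2L * cout, cout),
    norm_f = norm_init(cout)
  )
  if (cin != cout) par$proj <- conv_init(1L, cin, cout)
  par
}

block_forward <- function(x, par) {
  ca <- conv_forward(x, par$conv_a)
  na <- norm_forward(ca$out, par$norm_a)
  ra <- relu_forward(na$out)
  cb <- conv_forward(x, par$conv_b)
  nb <- norm_forward(cb$out, par$norm_b)
  rb <- relu_forward(nb$out)
  hc <- concat_channels(ra$out, rb$out)
  cf <- conv_forward(hc, par$fuse)
  nf <- norm_forward(cf$out, par$norm_f)
  if (!is.null(par$proj)) {
    pr <- conv_forward(x, par$proj)
    s <- pr$out
  } else {
    pr <- NULL
    s <- x
  }
  ro <- relu_forward(nf$out + s)
  list(out = ro$out,
       cache = list(ca = ca, na = na, ra = ra, cb = cb, nb = nb, rb = rb,
                    cf = cf, nf = nf, pr = pr, ro = ro,
                    cout = dim(ra$out)[3L]))
}

block_backward <- function(dy, cache, par) {
  dsum <- relu_backward(dy, cache$ro)
  grads <- list()
  nf <- norm_backward(dsum, cache$nf, par$norm_f)
  grads$norm_f <- nf$grads
  cf <- conv_backward(nf$dx, cache$cf, par$fuse)
  grads$fuse <- cf$grads
  co <- cache$cout
  d_ra <- cf$dx[, , seq_len(co), drop = FALSE]
  d_rb <- cf$dx[, , co + seq_len(co), drop = FALSE]
  na <- norm_backward(relu_backward(d_ra, cache$ra), cache$na, par$norm_a)
  grads$norm_a <- na$grads
  ca <- conv_backward(na$dx, cache$ca, par$conv_a)
  grads$conv_a <- ca$grads
  nb <- norm_backward(relu_backward(d_rb, cache$rb), cache$nb, par$norm_b)
  grads$norm_b <- nb$grads
  cb <- conv_backward(nb$dx, cache$cb, par$conv_b)
  grads$conv_b <- cb$grads
  dx <- ca$dx + cb$dx
  if (!is.null(par$proj)) {
    pr <- conv_backward(dsum, cache$pr, par$proj)
    grads$proj <- pr$grads
    dx <- dx + pr$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

#' Build the multi-scale residual U-Net
#'
#' @param config a [model_config()].
#' @return an object of class \code{msunet} holding the configuration and
#'   the (seeded, He-initialized) parameters.
#' @export
build_model <- function(config) {
  if (!inherits(config, "model_config")) config <- do.call(model_config, config)
  set.seed(config$seed)
  depth <- config$depth; base <- config$base_channels
  ch <- base * 2^(seq_len(depth) - 1L)
  enc <- vector("list", depth)
  cin <- config$in_channels
  for (l in seq_len(depth)) {
    enc[[l]] <- block_init(cin, ch[l], config$kernels)
    cin <- ch[l]
  }
  bott <- block_init(ch[depth], 2L * ch[depth], config$kernels)
  dec <- vector("list", depth)
  up <- vector("list", depth)
  incoming <- 2L * ch[depth]
  for (l in rev(seq_len(depth))) {
    up[[l]] <- conv_init(1L, incoming, ch[l])
    dec[[l]] <- block_init(2L * ch[l], ch[l], config$kernels)
    incoming <- ch[l]
  }
  head <- conv_init(1L, ch[1L], 1L)
  structure(list(config = config,
                 params = list(enc = enc, bott = bott, up = up, dec = dec,
                               head = head)),
            class = "msunet")
}

#' @export
print.msunet <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(
    "<msunet> depth %d, base %d channels, kernels %dx%d + %dx%d, %d parameters\n",
    cfg$depth, cfg$base_channels, cfg$kernels[1L], cfg$kernels[1L],
    cfg$kernels[2L], cfg$kernels[2L], np))
  invisible(x)
}

# forward pass on a normalized H x W (x C) input; returns logits (+ caches)
model_forward <- function(model, x, keep_cache = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  p <- model$params; depth <- model$config$depth
  skips <- vector("list", depth)
  caches <- if (keep_cache) list(enc = vector("list", depth),
                                 pool = vector("list", depth),
                                 up = vector("list", depth),
                                 ups = vector("list", depth),
                                 dec = vector("list", depth)) else NULL
  h <- x
  for (l in seq_len(depth)) {
    bf <- block_forward(h, p$enc[[l]])
    skips[[l]] <- bf$out
    pf <- maxpool_forward(bf$out)
    h <- pf$out
    if (keep_cache) { caches$enc[[l]] <- bf$cache; caches$pool[[l]] <- pf }
  }
  bf <- block_forward(h, p$bott)
  h <- bf$out
  if (keep_cache) caches$bott <- bf$cache
  for (l in rev(seq_len(depth))) {
    uf <- upsample_forward(h)
    cf <- conv_forward(uf$out, p$up[[l]])
    hc <- concat_channels(cf$out, skips[[l]])
    df <- block_forward(hc, p$dec[[l]])
    h <- df$out
    if (keep_cache) {
      caches$ups[[l]] <- uf; caches$up[[l]] <- cf; caches$dec[[l]] <- df$cache
    }
  }
  hf <- conv_forward(h, p$head)
  if (keep_cache) caches$head <- hf
  list(logits = hf$out, caches = caches)
}

# full backward pass; dlogits has the shape of the logits
model_backward <- function(model, dlogits, caches) {
  p <- model$params; depth <- model$config$depth
  grads <- list(enc = vector("list", depth), up = vector("list", depth),
                dec = vector("list", depth))
  hb <- conv_backward(dlogits, caches$head, p$head)
  grads$head <- hb$grads
  dh <- hb$dx
  dskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    db <- block_backward(dh, caches$dec[[l]], p$dec[[l]])
    grads$dec[[l]] <- db$grads
    nup <- p$up[[l]]$cout
    d_up <- db$dx[, , seq_len(nup), drop = FALSE]
    dskips[[l]] <- db$dx[, , nup + seq_len(dim(db$dx)[3L] - nup), drop = FALSE]
    ub <- conv_backward(d_up, caches$up[[l]], p$up[[l]])
    grads$up[[l]] <- ub$grads
    dh <- upsample_backward(ub$dx, caches$ups[[l]])
  }
  bb <- block_backward(dh, caches$bott, p$bott)
  grads$bott <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(depth))) {
    dpool <- maxpool_backward(dh, caches$pool[[l]])
    eb <- block_backward(dpool + dskips[[l]], caches$enc[[l]], p$enc[[l]])
    grads$enc[[l]] <- eb$grads
    dh <- eb$dx
  }
  grads
}

reflect_pad_to <- function(m, mult) {
  H <- nrow(m); W <- ncol(m)
  Hp <- ceiling(H / mult) * mult; Wp <- ceiling(W / mult) * mult
  if (Hp > 2L * H - 1L || Wp > 2L * W - 1L)
    stop("image too small to pad to a multiple of ", mult)
  ri <- c(seq_len(H), H - seq_len(Hp - H))
  ci <- c(seq_len(W), W - seq_len(Wp - W))
  m[ri, ci, drop = FALSE]
}

#' Segment an image with a trained model
#'
#' The image is normalized to \code{[0, 1]}, reflect-padded so both
#' dimensions are multiples of \code{2^depth}, passed through the network,
#' cropped back, and thresholded (strict \code{>}).
#'
#' @param model an \code{msunet} from [build_model()] or [train()].
#' @param image an [organoid_image()] or a numeric matrix in \code{[0,255]}.
#' @param threshold binarization threshold in \code{(0, 1)}.
#' @return list: \code{prob} (probability map, same shape as the input) and
#'   \code{mask} (logical matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  px <- if (inherits(image, "organoid_image")) image$pixels else as.matrix(image)
  H <- nrow(px); W <- ncol(px)
  mult <- 2L^model$config$depth
  if (H < mult || W < mult)
    stop("image smaller than 2^depth = ", mult, " in some dimension")
  xin <- reflect_pad_to(px / 255, mult)
  fw <- model_forward(model, xin, keep_cache = FALSE)
  prob <- sigmoid(fw$logits[, , 1L])
  prob <- prob[seq_len(H), seq_len(W), drop = FALSE]
  list(prob = prob, mask = prob > threshold)
}

#' Save / load a model checkpoint
#' @param model an \code{msunet}.
#' @param path checkpoint path (RDS).
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "msunet")) stop("not an msunet checkpoint: ", path)
  m
}
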