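# Low-level neural network layers.
#
# Feature maps are 3-D arrays H x W x C. Convolution is evaluated as a sum
# of k^2 shifted matrix products (one (H*W) x Cin by Cin x Cout GEMM per
# kernel offset), which keeps all heavy arithmetic inside BLAS; backward
# passes are the exact adjoints of the forward computations. Weights for a
# k x k convolution are stored as a (k^2 * Cin) x Cout matrix whose rows are
# ordered offset-major, then input-channel.

conv_init <- function(k, cin, cout) {
  fan_in <- k * k * cin
  list(w = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                  k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

norm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

pad_zero <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L]))
  xp[p + seq_len(d[1L]), p + seq_len(d[2L]), ] <- x
  xp
}

conv_forward <- function(x, par) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; cin <- par$cin
  k <- par$k; p <- (k - 1L) %/% 2L
  xp <- pad_zero(x, p)
  out <- matrix(rep(par$b, each = H * W), H * W, par$cout)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    blk <- xp[i:(i + H - 1L), j:(j + W - 1L), , drop = FALSE]
    dim(blk) <- c(H * W, cin)
    rows <- (((j - 1L) * k + (i - 1L)) * cin) + seq_len(cin)
    out <- out + blk %*% par$w[rows, , drop = FALSE]
  }
  dim(out) <- c(H, W, par$cout)
  list(out = out, x = x)
}

conv_backward <- function(dy, cache, par) {
  x <- cache$x
  d <- dim(x); H <- d[1L]; W <- d[2L]; cin <- par$cin
  k <- par$k; p <- (k - 1L) %/% 2L
  xp <- pad_zero(x, p)
  dim(dy) <- c(H * W, par$cout)
  dw <- matrix(0, nrow(par$w), par$cout)
  dxp <- array(0, dim(xp))
  for (j in seq_len(k)) for (i in seq_len(k)) {
    blk <- xp[i:(i + H - 1L), j:(j + W - 1L), , drop = FALSE]
    dim(blk) <- c(H * W, cin)
    rows <- (((j - 1L) * k + (i - 1L)) * cin) + seq_len(cin)
    dw[rows, ] <- crossprod(blk, dy)
    dblk <- dy %*% t(par$w[rows, , drop = FALSE])
    dim(dblk) <- c(H, W, cin)
    dxp[i:(i + H - 1L), j:(j + W - 1L), ] <-
      dxp[i:(i + H - 1L), j:(j + W - 1L), , drop = FALSE] + dblk
  }
  dx <- dxp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
  list(dx = dx, grads = list(w = dw, b = colSums(dy)))
}

NORM_EPS <- 1e-5

# per-sample, per-channel (instance) normalization over the spatial plane
norm_forward <- function(x, par) {
  d <- dim(x); n <- d[1L] * d[2L]; C <- d[3L]
  xm <- x; dim(xm) <- c(n, C)
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  istd <- 1 / sqrt(v + NORM_EPS)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  dim(y) <- d
  list(out = y, xhat = xhat, istd = istd, dims = d)
}

norm_backward <- function(dy, cache, par) {
  d <- cache$dims; n <- d[1L] * d[2L]; C <- d[3L]
  dim(dy) <- c(n, C)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  m1 <- colMeans(dy)
  m2 <- colMeans(dy * xhat)
  dx <- sweep(dy, 2L, m1, "-") - sweep(xhat, 2L, m2, "*")
  dx <- sweep(dx, 2L, par$gamma * cache$istd, "*")
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  subs <- list(x[ro, co, , drop = FALSE], x[re, co, , drop = FALSE],
               x[ro, ce, , drop = FALSE], x[re, ce, , drop = FALSE])
  cur <- subs[[1L]]
  arg <- array(1L, dim(cur))
  for (kk in 2:4) {
    better <- subs[[kk]] > cur
    cur[better] <- subs[[kk]][better]
    arg[better] <- kk
  }
  list(out = cur, arg = arg, dims = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  idx <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (kk in 1:4) {
    sel <- cache$arg == kk
    g <- array(0, dim(dy)); g[sel] <- dy[sel]
    dx[idx[[kk]][[1L]], idx[[kk]][[2L]], ] <- g
  }
  dx
}

upsample_forward <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
         drop = FALSE]
  list(out = y, dims = d)
}

upsample_backward <- function(dy, cache) {
  d <- cache$dims
  ro <- seq(1L, 2L * d[1L], 2L); re <- ro + 1L
  co <- seq(1L, 2L * d[2L], 2L); ce <- co + 1L
  dy[ro, co, , drop = FALSE] + dy[re, co, , drop = FALSE] +
    dy[ro, ce, , drop = FALSE] + dy[re, ce, , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a
  out[, , da[3L] + seq_len(db[3L])] <- b
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))
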