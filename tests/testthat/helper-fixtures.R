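# shared fixture builders; everything is generated in code at test time

# reduced-scale study scene: 256 x 256 frame, six organoids, two
# out-of-focus distractors, 1.5 um/px
study_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(height = 256L, width = 256L, n_organoids = 6L,
         diameter_median_um = 60, diameter_range_um = c(25, 120),
         ecc_range = c(0, 0.7), n_outfocus_distractors = 2L,
         um_per_px = 1.5, seed = seed),
    list(...))
  do.call(sim_config, args)
}

study_scene <- function(seed, ...) generate_scene(study_config(seed, ...))

as_pair <- function(scene) list(image = scene$image$pixels, mask = scene$mask)

# tiny scenes for fast training smoke tests
tiny_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(height = 64L, width = 64L, n_organoids = 2L,
         diameter_median_um = 26, diameter_range_um = c(18, 38),
         ecc_range = c(0, 0.5), n_outfocus_distractors = 0L,
         um_per_px = 1.5, noise_sd = 5, seed = seed),
    list(...))
  do.call(sim_config, args)
}

tiny_train_sets <- function(n_train = 3L, n_val = 2L, seed0 = 900L) {
  tr <- lapply(seq_len(n_train),
               function(i) as_pair(generate_scene(tiny_config(seed0 + i))))
  va <- lapply(seq_len(n_val),
               function(i) as_pair(generate_scene(tiny_config(seed0 + 50L + i))))
  list(train = tr, val = va)
}

# background holes = background components that do not touch the border
count_enclosed_holes <- function(mask) {
  bg <- !mask
  lab <- orgseg:::label8(bg)
  if (max(lab) == 0L) return(0L)
  H <- nrow(mask); W <- ncol(mask)
  border_labels <- unique(c(lab[1L, ], lab[H, ], lab[, 1L], lab[, W]))
  sum(!seq_len(max(lab)) %in% border_labels[border_labels > 0L])
}

# independent brute-force statistics oracles
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

brute_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

brute_ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - my)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

brute_dice <- function(p, g) {
  s <- sum(p) + sum(g)
  if (s == 0) 1 else 2 * sum(p & g) / s
}
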