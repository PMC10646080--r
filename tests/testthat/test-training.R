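test_that("dice loss matches its closed forms", {
  g <- matrix(c(1, 1, 0, 0), 2, 2)
  # perfect binary prediction: loss <= eps / (2|g| + eps)
  expect_lte(dice_loss(g, g), 1 / (2 * sum(g) + 1))
  # total miss: only the smoothing term keeps it below 1
  expect_equal(dice_loss(1 - g, g), 1 - 1 / (sum(1 - g) + sum(g) + 1))
  # constant 0.5 vs half-foreground on 4 px: 1 - (2*1 + 1)/(2 + 2 + 1)
  p <- matrix(0.5, 2, 2)
  expect_equal(dice_loss(p, g), 0.4)
  expect_error(dice_loss(matrix(0.5, 2, 3), g), "shape")
  # bounds
  expect_gte(dice_loss(p, g), 0)
  expect_lte(dice_loss(p, g), 1)
})

test_that("cross-entropy loss matches its closed forms", {
  g <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(cross_entropy_loss(g, g), -log(1 - 1e-7), tolerance = 1e-9)
  expect_equal(cross_entropy_loss(matrix(0.5, 2, 2), g), log(2),
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(matrix(0.8, 1, 1), matrix(1, 1, 1)),
               -log(0.8), tolerance = 1e-12)
})

test_that("compound loss is the sum of its parts and dominates each", {
  set.seed(5)
  p <- matrix(runif(9), 3, 3)
  g <- matrix(rbinom(9, 1, 0.5), 3, 3)
  expect_equal(compound_loss(p, g),
               cross_entropy_loss(p, g) + dice_loss(p, g))
  expect_gte(compound_loss(p, g),
             max(cross_entropy_loss(p, g), dice_loss(p, g)))
})

test_that("compound loss gradient matches finite differences on a 3x3 toy", {
  set.seed(6)
  p <- matrix(runif(9, 0.1, 0.9), 3, 3)
  g <- matrix(rbinom(9, 1, 0.5), 3, 3)
  an <- compound_loss_grad(p, g)
  eps <- 1e-6
  for (i in seq_len(9)) {
    p1 <- p; p1[i] <- p[i] + eps
    p2 <- p; p2[i] <- p[i] - eps
    fd <- (compound_loss(p1, g) - compound_loss(p2, g)) / (2 * eps)
    expect_equal(an[i], fd, tolerance = 1e-4)
  }
})

test_that("augmentation respects identity, involution and area contracts", {
  scn <- generate_scene(tiny_config(41L))
  img <- scn$image$pixels; msk <- scn$mask
  # all magnitudes zero -> exact identity
  idcfg <- train_config(flip_p = 0, rot_range = 0, scale_range = c(1, 1),
                        translate_frac = 0, blur_sigma_range = c(0, 0))
  out <- augment(img, msk, idcfg)
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)
  # deterministic double flip is an involution
  flcfg <- train_config(flip_p = 1, rot_range = 0, scale_range = c(1, 1),
                        translate_frac = 0, blur_sigma_range = c(0, 0))
  once <- augment(img, msk, flcfg)
  twice <- augment(once$image, once$mask, flcfg)
  expect_identical(twice$image, img)
  expect_identical(twice$mask, msk)
  # 90 degree rotation preserves mask area exactly (square frame)
  rot <- orgseg:::warp_pair(img, msk, pi / 2, 1, 0, 0)
  expect_equal(sum(rot$mask), sum(msk))
  expect_error(augment(img, msk[1:10, ]), "shape")
})

test_that("training improves validation DSC and selects the best epoch", {
  sets <- tiny_train_sets(4L, 2L, seed0 = 700L)
  model <- build_model(model_config(depth = 1L, base_channels = 4L, seed = 1L))
  cfg <- train_config(crop = 48L, batch = 2L, lr = 0.05, epochs = 10L,
                      rot_range = 90, blur_sigma_range = c(0, 0.5), seed = 3L)
  res <- train(model, sets$train, sets$val, cfg)
  h <- res$history
  expect_equal(nrow(h), 10L)
  expect_gt(h$val_dsc[10L], h$val_dsc[1L])
  expect_equal(attr(h, "best_epoch"), which.max(h$val_dsc))
  # loss decreases on average over epoch windows
  expect_lt(mean(tail(h$loss_total, 3)), mean(head(h$loss_total, 3)))
})

test_that("zero-epoch training is the identity and training is deterministic", {
  sets <- tiny_train_sets(2L, 1L, seed0 = 800L)
  model <- build_model(model_config(depth = 1L, base_channels = 2L, seed = 2L))
  res0 <- train(model, sets$train, sets$val,
                train_config(crop = 32L, epochs = 0L))
  expect_identical(res0$model$params, model$params)
  expect_equal(nrow(res0$history), 0L)

  cfg <- train_config(crop = 32L, batch = 2L, lr = 0.05, epochs = 2L, seed = 7L)
  r1 <- train(model, sets$train, sets$val, cfg)
  r2 <- train(model, sets$train, sets$val, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)

  expect_error(train(model, list(), sets$val, cfg), "empty")
  expect_error(train(model, sets$train, sets$val,
                     train_config(crop = 512L, epochs = 1L)),
               "crop larger")
})
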