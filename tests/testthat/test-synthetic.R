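test_that("rasterized ellipses match their analytic geometry", {
  m <- rasterize_ellipse(c(128, 128), c(50, 50), 0, c(256, 256))
  expect_lt(abs(sum(m) - pi * 50^2) / (pi * 50^2), 0.01)

  cfg <- study_config(5L)
  scn <- generate_scene(cfg)
  org <- scn$objects[!scn$objects$is_distractor, ]
  # recorded analytic invariants: area pi*a*b, ecc sqrt(1 - b^2/a^2)
  expect_equal(org$area_px, pi * org$a * org$b)
  expect_equal(org$eccentricity, sqrt(1 - (org$b / org$a)^2))

  # circle: measured eccentricity ~0; a = 2b: ecc sqrt(3)/2
  circ <- rasterize_ellipse(c(64, 64), c(20, 20), 0.3, c(128, 128))
  mm <- measure_object(label_contours(circ), 1L)
  expect_lt(mm$eccentricity, 0.05)
  expect_equal(sqrt(1 - (1 / 2)^2), sqrt(3) / 2)  # a = 2b closed form
  expect_error(rasterize_ellipse(c(10, 10), c(0, 0), 0, c(20, 20)),
               "degenerate")
})

test_that("scenes have exact ground truth excluding distractors", {
  # empty scene is pure background
  empty <- generate_scene(study_config(3L, n_organoids = 0L,
                                       n_outfocus_distractors = 0L))
  expect_false(any(empty$mask))

  scn <- study_scene(7L)
  org <- scn$objects[!scn$objects$is_distractor, ]
  # truth mask = union of non-distractor rasterizations, exactly
  ref <- matrix(FALSE, 256, 256)
  for (i in seq_len(nrow(org)))
    ref <- ref | rasterize_ellipse(c(org$center_row[i], org$center_col[i]),
                                   c(org$a[i], org$b[i]), org$orientation[i],
                                   c(256, 256))
  expect_identical(scn$mask, ref)

  # non-overlapping organoids -> one component each
  scn5 <- generate_scene(study_config(9L, n_organoids = 5L,
                                      n_outfocus_distractors = 0L))
  expect_equal(max(orgseg:::label8(scn5$mask)), 5L)

  # analytic total area matches the pixel count within 2 %
  in_frame <- !org$touches_border
  expect_lt(abs(sum(org$area_px[in_frame]) - sum(ref)) / sum(ref), 0.02)
})

test_that("scene generation is deterministic in (config, seed)", {
  a <- study_scene(11L)
  b <- study_scene(11L)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  expect_identical(a$objects, b$objects)
})

test_that("growth series obey the viability-proportionality contract", {
  cfg <- tiny_config(13L)
  # noiseless doubling: viability doubles exactly day over day
  gs <- generate_growth_series(cfg, days = 4L, daily_growth = 2,
                               noise = 0, n_wells = 1L)
  v <- gs$records$viability
  expect_equal(v[-1L] / v[-4L], rep(2, 3))
  # noiseless: viability is exactly proportional to total true area
  expect_equal(brute_pearson(gs$records$total_area_px, v), 1)

  # 5 days x 3 wells at 5 % noise still correlates strongly
  gs2 <- generate_growth_series(tiny_config(17L), days = 5L,
                                daily_growth = 2, noise = 0.05, n_wells = 3L)
  expect_gte(pearson(gs2$records$total_area_px,
                     gs2$records$viability)$r, 0.95)

  expect_error(generate_growth_series(cfg, days = 1L, daily_growth = 2),
               "days")
  expect_error(generate_growth_series(cfg, days = 3L, daily_growth = 0),
               "daily_growth")
})

test_that("growth tapering after the plateau day slows the series", {
  gs <- generate_growth_series(tiny_config(19L), days = 5L,
                               daily_growth = 2, noise = 0,
                               n_wells = 1L, plateau_day = 5L,
                               plateau_growth = 1.05)
  a <- gs$records$total_area_px
  expect_equal(a[2:4] / a[1:3], rep(2, 3))
  expect_equal(a[5] / a[4], 1.05)
})

test_that("rendered growth scenes carry day/well metadata", {
  gs <- generate_growth_series(tiny_config(23L), days = 2L, daily_growth = 1.5,
                               noise = 0, n_wells = 1L, render = TRUE)
  scn <- gs$scenes[[1L]][[2L]]
  expect_equal(scn$image$meta$day, 2L)
  expect_true(any(scn$mask))
})
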