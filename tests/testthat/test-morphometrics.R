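test_that("a digitized circle measures like a circle", {
  m <- rasterize_ellipse(c(128, 128), c(50, 50), 0, c(256, 256))
  mm <- measure_object(label_contours(m), 1L)
  expect_lt(abs(mm$area_px - pi * 50^2) / (pi * 50^2), 0.01)
  expect_lte(mm$eccentricity, 0.05)
  expect_lt(abs(mm$circularity - 1), 0.05)
  expect_gte(mm$solidity, 0.98)
  expect_lt(abs(mm$equiv_diameter_px - 100) / 100, 0.01)
  expect_lt(abs(mm$perimeter_px - 2 * pi * 50) / (2 * pi * 50), 0.03)
})

test_that("a 2:1 ellipse matches its closed-form geometry", {
  m <- rasterize_ellipse(c(150, 150), c(100, 50), 0.4, c(300, 300))
  mm <- measure_object(label_contours(m), 1L)
  expect_lt(abs(mm$area_px - pi * 100 * 50) / (pi * 100 * 50), 0.02)
  expect_lt(abs(mm$eccentricity - sqrt(3) / 2), 0.05)
  expect_lt(abs(mm$major_axis_px - 200) / 200, 0.03)
  expect_lt(abs(mm$minor_axis_px - 100) / 100, 0.03)
})

test_that("a solid square has solidity exactly 1", {
  m <- matrix(FALSE, 40, 40); m[10:29, 12:31] <- TRUE
  mm <- measure_object(label_contours(m), 1L)
  expect_identical(mm$solidity, 1)
  expect_identical(mm$area_px, 400L)
})

test_that("unit conversion scales lengths, areas, and nothing else", {
  m <- rasterize_ellipse(c(60, 60), c(30, 20), 1, c(120, 120))
  lc <- label_contours(m)
  px <- measure_objects(lc, "img", um_per_px = NULL)
  expect_true(all(is.na(px$area_um2)))
  id <- measure_objects(lc, "img", um_per_px = 1)
  expect_equal(id$area_um2, id$area_px)
  two <- measure_objects(lc, "img", um_per_px = 2)
  expect_equal(two$area_um2, two$area_px * 4)
  expect_equal(two$perimeter_um, two$perimeter_px * 2)
  expect_equal(two$eccentricity, id$eccentricity)
  expect_equal(two$solidity, id$solidity)
  df <- data.frame(area_px = 100, equiv_diameter_px = 1, perimeter_px = 1,
                   major_axis_px = 1, minor_axis_px = 1)
  expect_equal(convert_units(df, 2)$area_um2, 400)
  expect_error(convert_units(df, -1), "um_per_px")
})

test_that("image summaries aggregate and are order-invariant", {
  rec <- data.frame(image_id = "x", object_id = 1:3,
                    area_px = c(10, 20, 30), area_um2 = c(10, 20, 30) * 4,
                    perimeter_px = c(5, 6, 7), perimeter_um = c(10, 12, 14),
                    eccentricity = c(0.1, 0.5, 0.9))
  s <- summarize_image(rec)
  expect_equal(s$count, 3L)
  expect_equal(s$total_area_px, 60)
  expect_equal(s$mean_eccentricity, 0.5)
  expect_equal(summarize_image(rec[c(3, 1, 2), ])[, -1],
               s[, -1])
  one <- summarize_image(rec[2, ])
  expect_equal(one$mean_eccentricity, 0.5)
  empty <- summarize_image(rec[0, ], image_id = "e")
  expect_equal(empty$count, 0L)
  expect_equal(empty$total_area_px, 0)
  expect_true(is.na(empty$mean_eccentricity))
})

test_that("metrics are scale-equivariant and rotation-invariant", {
  base <- measure_object(label_contours(
    rasterize_ellipse(c(100, 100), c(45, 30), 0.3, c(200, 200))), 1L)
  dbl <- measure_object(label_contours(
    rasterize_ellipse(c(200, 200), c(90, 60), 0.3, c(400, 400))), 1L)
  expect_lt(abs(dbl$major_axis_px / base$major_axis_px - 2), 0.05)
  expect_lt(abs(dbl$area_px / base$area_px - 4), 0.05)
  for (metric in c("eccentricity", "circularity", "roundness", "solidity"))
    expect_lt(abs(dbl[[metric]] - base[[metric]]), 0.05)
  rot <- measure_object(label_contours(
    rasterize_ellipse(c(100, 100), c(45, 30), 0.3 + pi / 3, c(200, 200))), 1L)
  for (metric in c("eccentricity", "circularity", "roundness", "solidity"))
    expect_lt(abs(rot[[metric]] - base[[metric]]), 0.05)
  expect_lt(abs(rot$perimeter_px / base$perimeter_px - 1), 0.05)
  expect_gte(base$major_axis_px, base$minor_axis_px)
})

test_that("an empty region is an error", {
  lc <- label_contours(matrix(FALSE, 10, 10))
  expect_error(measure_object(labeled_contours(matrix(0L, 5, 5), list()), 1L))
  expect_equal(nrow(measure_objects(lc)), 0L)
})
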