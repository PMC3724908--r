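test_that("delete_explant fills with the modal background and reports the area", {
  img <- image_grid(matrix(50L, 6, 6))
  bits <- matrix(FALSE, 6, 6); bits[2:3, 2:6] <- TRUE  # 10 px
  out <- delete_explant(img, region_mask(bits))
  expect_equal(out$area$pixels, 10L)
  expect_true(all(out$image$pixels == 50L))
  expect_true(all(img$pixels == 50L))  # input untouched

  empty <- region_mask(matrix(FALSE, 6, 6))
  out0 <- delete_explant(img, empty)
  expect_identical(out0$image$pixels, img$pixels)
  expect_equal(out0$area$pixels, 0L)

  expect_error(delete_explant(img, region_mask(matrix(TRUE, 6, 6))),
               "entire image")
  expect_error(delete_explant(img, region_mask(matrix(FALSE, 3, 3))),
               "do not match")

  # generator ground truth: deleted-area pixel count equals the true
  # (hole-free ellipse) explant after the same hole filling the pipeline does
  s <- generate_sample(seed = 21, noise_sd = 0)
  wand <- fill_holes(magic_wand(s$image, s$seed_xy, 0.30))
  del <- delete_explant(s$image, wand)
  expect_equal(del$area$pixels, s$true_explant$pixel_count)
})

test_that("fixed thresholding and polarity follow the documented <=/> convention", {
  img <- image_grid(matrix(as.integer(rbind(c(50, 150), c(99, 101))), 2, 2))
  dark <- threshold_sprouts(img, "fixed", 100, "dark_objects")
  expect_equal(dark$threshold_used, 100L)
  expect_equal(dark$mask$pixel_count, 2)
  expect_true(all(img$pixels[dark$mask$bits] %in% c(50L, 99L)))

  bright <- threshold_sprouts(img, "fixed", 100, "bright_objects")
  expect_identical(bright$mask$bits, !dark$mask$bits)

  expect_error(threshold_sprouts(img, "fixed", 300), "out of range")
  expect_error(threshold_sprouts(img, "fixed"), "fixed_value")
})

test_that("otsu equals the exhaustive inter-class-variance oracle", {
  # two-valued image: 40% at 30, 60% at 200
  v <- c(rep(30L, 40), rep(200L, 60))
  img <- image_grid(matrix(v, 10, 10))
  # any cut in [30, 199] separates the classes; ties resolve to the lowest
  t_pkg <- otsu_threshold(img)
  expect_gte(t_pkg, 30); expect_lt(t_pkg, 200)
  res <- threshold_sprouts(img, "otsu", polarity = "dark_objects")
  expect_equal(res$mask$pixel_count, 40)
  expect_true(all(img$pixels[res$mask$bits] == 30L))
  expect_identical(t_pkg, otsu_oracle(img$pixels, 8))

  # random histograms
  for (s in 1:8) {
    set.seed(500 + s)
    m <- matrix(as.integer(pmin(255, pmax(0, round(c(rnorm(60, 70, 15),
                                                     rnorm(84, 190, 20)))))), 12, 12)
    gi <- image_grid(m)
    expect_identical(otsu_threshold(gi), otsu_oracle(m, 8))
  }

  expect_error(otsu_threshold(image_grid(matrix(7L, 3, 3))),
               "degenerate histogram")
})

test_that("otsu agrees with an independent library implementation", {
  skip_if_not_installed("EBImage")
  set.seed(77)
  m <- matrix(as.integer(pmin(255, pmax(0, round(c(rnorm(200, 60, 12),
                                                   rnorm(312, 180, 25)))))), 16, 32)
  ours <- otsu_threshold(image_grid(m))
  ref <- EBImage::otsu(EBImage::Image(t(m) / 255), range = c(0, 1), levels = 256)
  # EBImage returns the cut as a gray fraction; same split up to one bin
  expect_lte(abs(ours - round(ref * 255)), 2)
})

test_that("polygon validation, point-in-polygon and rasterization are consistent", {
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(polygon_roi(rbind(c(0, 0), c(2, 2), c(4, 4))), "zero area")
  # bowtie with non-degenerate shoelace area
  expect_error(polygon_roi(rbind(c(0, 0), c(3, 3), c(3, 0), c(0, 2))),
               "self-intersecting")

  sq <- polygon_roi(rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0)))
  expect_equal(sq$area, 4)

  # brute-force oracle over all 25 centers of a 5x5 image
  grid <- expand.grid(x = 0:4, y = 0:4)
  want <- pip_oracle(grid$x, grid$y, sq$x, sq$y)
  got <- points_in_polygon(grid$x, grid$y, sq)
  expect_identical(got, want)
  expect_equal(sum(got), 9)  # inclusive boundary: centers 0..2 in both axes

  ras <- rasterize_polygon(sq, 5, 5)
  expect_equal(ras$pixel_count, 9)

  # random simple polygons vs the oracle
  for (s in 1:10) {
    set.seed(600 + s)
    ang <- sort(runif(7, 0, 2 * pi))
    r <- runif(7, 2, 6)
    poly <- polygon_roi(cbind(6 + r * cos(ang), 6 + r * sin(ang)))
    got <- points_in_polygon(grid$x, grid$y, poly)
    want <- pip_oracle(grid$x, grid$y, poly$x, poly$y)
    expect_identical(got, want)
  }
})

test_that("rasterized axis-aligned rectangles have exact pixel areas", {
  for (wh in list(c(3, 5), c(1, 7), c(6, 6))) {
    w <- wh[1]; h <- wh[2]
    # half-open box through pixel-center space: covers exactly w x h centers
    rect <- polygon_roi(rbind(c(-0.5, -0.5), c(-0.5, h - 0.5),
                              c(w - 0.5, h - 0.5), c(w - 0.5, -0.5)))
    expect_equal(rasterize_polygon(rect, 10, 10)$pixel_count, w * h)
  }
})

test_that("exclude_background keeps only pixels inside the polygon", {
  full <- region_mask(matrix(TRUE, 5, 5))
  sq <- polygon_roi(rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0)))
  kept <- exclude_background(full, sq)
  expect_equal(kept$pixel_count, 9)

  whole <- polygon_roi(rbind(c(0, 0), c(0, 4), c(4, 4), c(4, 0)))
  expect_equal(exclude_background(full, whole)$pixel_count, 25)

  expect_identical(exclude_background(full, NULL), full)

  big <- polygon_roi(rbind(c(-3, -3), c(-3, 9), c(9, 9), c(9, -3)))
  expect_warning(res <- exclude_background(full, big), "clipped")
  expect_equal(res$pixel_count, 25)
})

test_that("swift pipeline recovers ground truth and keeps masks disjoint", {
  # explant only, noiseless: zero sprout area
  s0 <- generate_sample(seed = 3, n_sprouts = 0, noise_sd = 0)
  q0 <- swift_quantify(s0$image, s0$seed_xy, threshold_method = "fixed",
                       fixed_value = 170)
  expect_equal(q0$sprout_area$pixels, 0L)

  # noiseless, high contrast: exact truth
  s <- generate_sample(seed = 4, noise_sd = 0)
  q <- swift_quantify(s$image, s$seed_xy, return_masks = TRUE)
  expect_equal(q$sprout_area$pixels, s$true_sprouts$pixel_count)
  expect_equal(q$explant_area$pixels, s$true_explant$pixel_count)
  expect_equal(sum(q$sprout_mask$bits & q$explant_mask$bits), 0)

  # determinism: bit-identical results on identical inputs
  q2 <- swift_quantify(s$image, s$seed_xy, return_masks = TRUE)
  expect_identical(q[names(q) != "overlay_path"], q2[names(q2) != "overlay_path"])

  # stage-prefixed errors
  expect_error(swift_quantify(s$image, c(-1, 0)), "^magic_wand:")
})

test_that("manual quantification subtracts the explant from the outline", {
  bits <- matrix(FALSE, 30, 30); bits[10:19, 10:19] <- TRUE  # 100 px explant
  explant <- region_mask(bits)
  outline <- polygon_roi(rbind(c(4.5, 4.5), c(4.5, 24.5), c(24.5, 24.5), c(24.5, 4.5)))
  # outline covers 20x20 = 400 centers (inclusive-boundary halves excluded by .5 offsets)
  q <- manual_quantify(outline, explant, 1000)
  expect_equal(q$method, "manual")
  expect_equal(q$sprout_area$pixels, 400 - 100)
  expect_equal(q$explant_area$mm2, 100)   # 1000 um/px: 1 px = 1 mm^2
  expect_equal(q$threshold_used, "manual-polygon")

  # outline identical to explant -> zero
  exact <- polygon_roi(rbind(c(9.5, 9.5), c(9.5, 19.5), c(19.5, 19.5), c(19.5, 9.5)))
  expect_equal(manual_quantify(exact, explant, 1)$sprout_area$pixels, 0)

  small <- polygon_roi(rbind(c(11.5, 11.5), c(11.5, 14.5), c(14.5, 14.5), c(14.5, 11.5)))
  expect_error(manual_quantify(small, explant, 1), "swapped")
})

test_that("manual hull outline upper-bounds the computerized readout", {
  for (seed in c(31, 32, 33)) {
    s <- generate_sample(seed = seed, noise_sd = 4)
    q <- swift_quantify(s$image, s$seed_xy, return_masks = TRUE)
    hull <- hull_outline(q$explant_mask, q$sprout_mask)
    qm <- manual_quantify(hull, q$explant_mask, 1.45)
    expect_gte(qm$sprout_area$pixels, q$sprout_area$pixels)
  }
})
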