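test_that("window clipping preserves or reduces polygons as expected", {
  rect <- polygon_roi(rbind(c(0, 0), c(100, 0), c(100, 40), c(0, 40)))
  w <- subfoveal_window(fovea_x_px = 50, lateral_scale_um_per_px = 30)
  # 750 um / 30 um per px = 25 px half-width: middle half of the rectangle
  clipped <- clip_to_window(rect, w)
  expect_equal(polygon_area(clipped, 1), 0.5 * polygon_area(rect, 1))
  inside <- polygon_roi(rbind(c(30, 5), c(70, 5), c(70, 35), c(30, 35)))
  expect_equal(polygon_area(clip_to_window(inside, w), 1),
               polygon_area(inside, 1))
  off <- polygon_roi(rbind(c(90, 0), c(100, 0), c(100, 10)))
  expect_error(clip_to_window(off, w), "overlap")
})

test_that("clipped area of a boundary-crossing triangle matches a
          rasterization oracle", {
  tri <- polygon_roi(rbind(c(10, 5), c(90, 20), c(30, 75)))
  w <- subfoveal_window(fovea_x_px = 40, lateral_scale_um_per_px = 30)
  clipped <- clip_to_window(tri, w)
  a_geom <- polygon_area(clipped, 1)
  # oracle: count pixel centres inside the triangle and the column band
  ras <- rasterize_polygon(tri, c(80, 100))
  cols <- matrix(rep(seq_len(100) - 0.5, each = 80), 80, 100)
  a_ras <- sum(ras & cols >= w$x_lo & cols < w$x_hi)
  expect_lt(abs(a_geom - a_ras) / a_ras, 0.01)
})

test_that("luminal mask is exactly dark-threshold AND TCA raster", {
  ch <- generate_choroid_phantom(choroid_phantom_spec(seed = 14))
  p <- niblack_params(15, 0.2, 0, polarity = "dark")
  lm <- luminal_mask(ch$image, ch$tca_polygon, p)
  oracle <- niblack_binarize(ch$image, p) &
    rasterize_polygon(ch$tca_polygon, dim(ch$image$pixels))
  expect_identical(lm, oracle)
  expect_error(luminal_mask(ch$image, ch$tca_polygon, niblack_params(15)),
               "dark")
})

test_that("a uniformly bright choroid has no luminal pixels", {
  img <- calibrated_image(matrix(200, 60, 80), c(0.8, 0.6))
  tca <- polygon_roi(rbind(c(5, 5), c(75, 5), c(75, 55), c(5, 55)))
  expect_false(any(luminal_mask(img, tca)))
})

test_that("noiseless phantom luminal segmentation agrees with ground truth
          on at least 95% of TCA pixels", {
  ch <- generate_choroid_phantom(choroid_phantom_spec(
    true_luminal_fraction = 0.65, noise_sd = 0, seed = 9))
  lm <- luminal_mask(ch$image, ch$tca_polygon)
  tca <- rasterize_polygon(ch$tca_polygon, dim(ch$image$pixels))
  agree <- sum((lm == ch$truth_luminal_mask)[tca]) / sum(tca)
  expect_gte(agree, 0.95)
})

test_that("CVI recovers the true luminal fraction, stays bounded and is
          monotone", {
  fr <- c(0.60, 0.65, 0.70)
  cvis <- vapply(fr, function(f) {
    ch <- generate_choroid_phantom(choroid_phantom_spec(
      true_luminal_fraction = f, noise_sd = 0, seed = 5))
    w <- subfoveal_window(ncol(ch$image$pixels) / 2, 7)
    cv <- compute_cvi(ch$image, ch$tca_polygon, w)
    expect_gte(cv$cvi_pct, 0); expect_lte(cv$cvi_pct, 100)
    expect_lte(cv$la_px, cv$tca_px)
    expect_lt(abs(cv$cvi_pct - 100 * ch$truth_luminal_fraction), 3)
    cv$cvi_pct
  }, numeric(1))
  expect_true(all(diff(cvis) > 0))
  # the healthy-control-like window: 69% luminal fraction
  ch <- generate_choroid_phantom(choroid_phantom_spec(
    true_luminal_fraction = 0.69, noise_sd = 0, seed = 2))
  w <- subfoveal_window(ncol(ch$image$pixels) / 2, 7)
  cv <- compute_cvi(ch$image, ch$tca_polygon, w)
  expect_gt(cv$cvi_pct, 66); expect_lt(cv$cvi_pct, 72)
})

test_that("an all-bright window yields CVI 0 and larger polygons never lose
          TCA pixels", {
  img <- calibrated_image(matrix(200, 60, 120), c(1.2, 0.6))
  w <- subfoveal_window(60, 10)  # 75 px half-width, clipped to polygon
  small <- polygon_roi(rbind(c(20, 10), c(100, 10), c(100, 40), c(20, 40)))
  big <- polygon_roi(rbind(c(10, 5), c(110, 5), c(110, 50), c(10, 50)))
  cv_small <- compute_cvi(img, small, w)
  cv_big <- compute_cvi(img, big, w)
  expect_equal(cv_small$cvi_pct, 0)
  expect_gte(cv_big$tca_px, cv_small$tca_px)
})
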