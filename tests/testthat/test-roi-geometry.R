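test_that("pixel scale reproduces the 320 px / 3 mm calibration", {
  expect_equal(pixels_per_mm(320, 3), 320 / 3)
  expect_identical(sprintf("%.2f", pixels_per_mm(320, 3)), "106.67")
  expect_equal(pixels_per_mm(100, 1), 100)
  expect_equal(pixels_per_mm(512, 6), 512 / 6)
  expect_error(pixels_per_mm(320, 0), "positive")
  expect_error(pixels_per_mm(320, -3), "positive")
})

test_that("square ROI has closed-form area, perimeter and circularity", {
  img <- calibrated_image(matrix(0, 320, 320), 3)
  s <- img$scale_px_per_mm[["x"]]
  sq <- polygon_roi(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  expect_equal(polygon_area(sq, s), 1)
  expect_equal(polygon_perimeter(sq, s), 4)
  fm <- faz_metrics(sq, img)
  expect_equal(fm$area_mm2, 1)
  expect_equal(fm$perimeter_mm, 4)
  expect_equal(fm$circularity, pi / 4)
  # orientation invariance
  rev_sq <- polygon_roi(sq$vertices[4:1, ])
  expect_equal(polygon_area(rev_sq, s), 1)
  # zero-length edge from a repeated vertex changes nothing
  dup <- polygon_roi(sq$vertices[c(1, 1, 2, 3, 4), ])
  expect_equal(polygon_perimeter(dup, s), 4)
  expect_equal(polygon_area(dup, s), 1)
})

test_that("a 256-gon matches circle closed forms and a 4:1 ellipse matches
          the Ramanujan oracle", {
  img <- calibrated_image(matrix(0, 320, 320), 3)
  s <- img$scale_px_per_mm[["x"]]
  r <- 0.357  # mm; pi r^2 ~ 0.40 mm^2
  roi <- circle_roi(r * s)
  fm <- faz_metrics(roi, img)
  expect_lt(abs(fm$area_mm2 - pi * r^2) / (pi * r^2), 0.005)
  expect_lt(abs(fm$perimeter_mm - 2 * pi * r) / (2 * pi * r), 0.001)
  expect_gte(fm$circularity, 0.99)
  # ellipse, semi-axes 4:1 (a = 1 mm, b = 0.25 mm)
  a <- 1; b <- 0.25
  ell <- ellipse_roi(a * s, b * s, n = 2048L)
  fme <- faz_metrics(ell, img)
  per_ram <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  circ_oracle <- 4 * pi * (pi * a * b) / per_ram^2
  expect_lt(abs(fme$circularity - circ_oracle), 0.01)
  expect_lt(abs(fme$circularity - 0.5365), 0.01)  # exact elliptic-integral value
})

test_that("circularity index reproduces printed group-mean ratios and the
          isoperimetric equality", {
  expect_equal(round(circularity_index(0.52, 2.87), 2), 0.79)
  expect_equal(round(circularity_index(0.41, 3.05), 2), 0.55)
  expect_equal(circularity_index(pi, 2 * pi), 1)
  expect_error(circularity_index(0, 1), "positive")
  expect_error(circularity_index(1, -1), "positive")
})

test_that("metrics are invariant to joint rescaling of coordinates and scale", {
  set.seed(101)
  for (i in 1:20) {
    roi <- random_convex_roi()
    f <- runif(1, 0.1, 10)
    roi2 <- polygon_roi(roi$vertices * f)
    expect_equal(polygon_area(roi, 50), polygon_area(roi2, 50 * f),
                 tolerance = 1e-9)
    expect_equal(polygon_perimeter(roi, 50), polygon_perimeter(roi2, 50 * f),
                 tolerance = 1e-9)
  }
})

test_that("circularity respects the isoperimetric bound on random polygons", {
  set.seed(202)
  for (i in 1:50) {
    roi <- random_convex_roi(n_pts = sample(5:25, 1))
    circ <- circularity_index(polygon_area(roi, 1), polygon_perimeter(roi, 1))
    expect_lte(circ, 1.01)
  }
})

test_that("circularity decreases as contour perturbation grows", {
  img <- calibrated_image(matrix(0, 320, 320), 3)
  s <- img$scale_px_per_mm[["x"]]
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ_at <- function(amp) {
    r <- (0.36 + amp * cos(3 * th) + 0.6 * amp * cos(5 * th)) * s
    roi <- polygon_roi(cbind(160 + r * cos(th), 160 + r * sin(th)))
    faz_metrics(roi, img)$circularity
  }
  circs <- vapply(seq(0, 0.12, by = 0.02), circ_at, numeric(1))
  expect_true(all(diff(circs) <= 1e-9))
})

test_that("degenerate and out-of-bounds ROIs are rejected", {
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1))), "3 vertices")
  line <- polygon_roi(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_error(polygon_area(line, 1), "degenerate")
  img <- calibrated_image(matrix(0, 32, 32), 1)
  out <- polygon_roi(rbind(c(-5, 0), c(10, 0), c(10, 10)))
  expect_error(faz_metrics(out, img), "bounds")
})

test_that("ROI JSON and CSV round-trip the vertex list", {
  roi <- random_convex_roi()
  tf <- tempfile(fileext = ".json")
  write_roi_json(roi, tf, image_name = "eye1.png", layer = "SCP")
  back <- read_roi_json(tf)
  expect_equal(back$vertices, roi$vertices)
  expect_identical(attr(back, "layer"), "SCP")
  tc <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = roi$vertices[, 1], y = roi$vertices[, 2]), tc,
            row.names = FALSE)
  expect_equal(read_roi_csv(tc)$vertices, roi$vertices)
})
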