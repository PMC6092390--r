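# Synthetic subfoveal choroid B-scan windows: dark elliptical lumens on a
# bright stromal background inside a traced total-choroidal-area polygon,
# with an exactly known luminal pixel fraction.

#' Specification of a choroid B-scan phantom
#'
#' Defaults emulate the subfoveal measurement window: about 1,500 um wide at
#' 7 um per pixel (216 columns) and 120 rows of choroid, lumens of mean
#' radius 6 px, stroma at 200 and lumens at 30 on the 8-bit scale.
#'
#' @param window_px window size `c(height, width)` in pixels.
#' @param lateral_scale_um_per_px lateral calibration, um per pixel.
#' @param true_luminal_fraction target dark-pixel fraction inside the TCA,
#'   in `[0, 1)`.
#' @param lumen_radius_px mean lumen blob radius, px.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param seed integer RNG seed.
#' @return Object of class `choroid_phantom_spec`.
#' @export
choroid_phantom_spec <- function(window_px = c(120L, 216L),
                                 lateral_scale_um_per_px = 7,
                                 true_luminal_fraction = 0.69,
                                 lumen_radius_px = 6,
                                 noise_sd = 8, seed = 1L) {
  window_px <- as.integer(window_px)
  if (length(window_px) != 2L || any(window_px < 16L))
    stop("`window_px` must be c(height, width), both >= 16")
  if (true_luminal_fraction < 0 || true_luminal_fraction >= 1)
    stop("`true_luminal_fraction` must be in [0, 1)")
  if (lateral_scale_um_per_px <= 0)
    stop("`lateral_scale_um_per_px` must be positive")
  if (lumen_radius_px < 1) stop("`lumen_radius_px` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(
    list(window_px = window_px,
         lateral_scale_um_per_px = lateral_scale_um_per_px,
         true_luminal_fraction = true_luminal_fraction,
         lumen_radius_px = lumen_radius_px,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "choroid_phantom_spec"
  )
}

# Pixel set of a rotated ellipse with semi-axes a, b centred at (cx, cy).
ellipse_pixels <- function(nr, nc, cx, cy, a, b, phi) {
  j <- seq(max(1L, floor(cx - max(a, b))), min(nc, ceiling(cx + max(a, b))))
  i <- seq(max(1L, floor(cy - max(a, b))), min(nr, ceiling(cy + max(a, b))))
  if (!length(i) || !length(j)) return(matrix(FALSE, nr, nc))
  xg <- matrix(j - 0.5, length(i), length(j), byrow = TRUE) - cx
  yg <- matrix(i - 0.5, length(i), length(j)) - cy
  u <- xg * cos(phi) + yg * sin(phi)
  v <- -xg * sin(phi) + yg * cos(phi)
  sub <- (u / a)^2 + (v / b)^2 <= 1
  out <- matrix(FALSE, nr, nc)
  out[i, j] <- sub
  out
}

#' Generate a choroid B-scan phantom
#'
#' Places random dark elliptical lumens inside the TCA polygon until the
#' dark-pixel fraction reaches the target; the last blobs are shrunk to the
#' remaining deficit so the achieved fraction lands within 0.02 of the
#' target. The reported truth fraction is recomputed from the final mask.
#'
#' @param spec a [choroid_phantom_spec()].
#' @return A list of class `choroid_phantom`: `image` ([calibrated_image()],
#'   isotropic at the lateral scale), `truth_luminal_mask`, `tca_polygon`,
#'   `truth_luminal_fraction`, `spec`.
#' @export
generate_choroid_phantom <- function(spec) {
  stopifnot(inherits(spec, "choroid_phantom_spec"))
  with_seed(spec$seed, {
    nr <- spec$window_px[1L]; nc <- spec$window_px[2L]
    inset <- 2
    tca <- polygon_roi(rbind(c(inset, inset), c(nc - inset, inset),
                             c(nc - inset, nr - inset), c(inset, nr - inset)))
    tca_raster <- rasterize_polygon(tca, c(nr, nc))
    n_tca <- sum(tca_raster)
    target <- spec$true_luminal_fraction
    if (target > 0.95)
      stop("true_luminal_fraction too high to place non-degenerate lumens")

    lum <- matrix(FALSE, nr, nc)
    if (target > 0) {
      r0 <- spec$lumen_radius_px
      tries <- 0L
      repeat {
        frac <- sum(lum) / n_tca
        if (frac >= target - 0.005) break
        deficit_px <- (target - frac) * n_tca
        r <- if (deficit_px < pi * r0^2) max(1, sqrt(deficit_px / pi)) else r0
        a <- r * stats::runif(1, 0.7, 1.3)
        b <- r^2 / a  # keep pi*a*b ~ pi*r^2
        e <- ellipse_pixels(nr, nc, stats::runif(1, inset, nc - inset),
                            stats::runif(1, inset, nr - inset),
                            a, b, stats::runif(1, 0, pi))
        lum <- lum | (e & tca_raster)
        tries <- tries + 1L
        if (tries > 20000L)
          stop("true_luminal_fraction too high to place non-degenerate lumens")
      }
    }

    achieved <- sum(lum) / n_tca
    if (abs(achieved - target) > 0.02)
      stop("achieved luminal fraction misses the target by more than 0.02")

    img <- matrix(90, nr, nc)   # tissue outside the traced choroid
    img[tca_raster] <- 200      # hyperreflective stroma
    img[lum] <- 30              # hyporeflective lumen
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(nr * nc, 0, spec$noise_sd)
    img <- round(pmin(pmax(img, 0), 255))

    extent_mm <- c(nc, nr) * spec$lateral_scale_um_per_px / 1000
    structure(
      list(image = calibrated_image(img, extent_mm),
           truth_luminal_mask = lum,
           tca_polygon = tca,
           truth_luminal_fraction = achieved,
           spec = spec),
      class = "choroid_phantom"
    )
  })
}
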