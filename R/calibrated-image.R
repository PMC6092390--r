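#' Calibrated grayscale image
#'
#' Bundles a 2-D grayscale pixel grid with its physical extent so that all
#' downstream quantities (areas, lengths, densities) can be expressed in
#' millimetres. En-face OCT angiography scans of the macula are typically
#' 320 x 320 pixels over 3 x 3 mm; choroidal B-scan windows carry a lateral
#' micrometre-per-pixel calibration instead.
#'
#' Coordinate convention: the pixel grid is a numeric matrix with rows running
#' top-to-bottom (y) and columns left-to-right (x). Continuous coordinates
#' span `[0, width_px] x [0, height_px]`; the centre of the pixel stored at
#' `pixels[i, j]` is at `(j - 0.5, i - 0.5)`. Polygon vertices may be
#' sub-pixel (continuous-valued).
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param extent_mm physical size as `c(width_mm, height_mm)`; a single value
#'   is recycled for square images.
#' @return An object of class `calibrated_image` with elements `pixels`,
#'   `extent_mm`, and per-axis `scale_px_per_mm`.
#' @examples
#' img <- calibrated_image(matrix(0, 320, 320), extent_mm = 3)
#' img$scale_px_per_mm  # 106.67 px/mm on both axes
#' @export
calibrated_image <- function(pixels, extent_mm) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  extent_mm <- as.numeric(extent_mm)
  if (length(extent_mm) == 1L) extent_mm <- c(extent_mm, extent_mm)
  if (length(extent_mm) != 2L || any(!is.finite(extent_mm)) ||
      any(extent_mm <= 0))
    stop("`extent_mm` must be one or two positive finite values")
  scale <- c(x = ncol(pixels) / extent_mm[1L],
             y = nrow(pixels) / extent_mm[2L])
  structure(
    list(pixels = pixels,
         extent_mm = c(x = extent_mm[1L], y = extent_mm[2L]),
         scale_px_per_mm = scale),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.3g x %.3g mm (%.2f px/mm)\n",
              nrow(x$pixels), ncol(x$pixels),
              x$extent_mm["x"], x$extent_mm["y"],
              x$scale_px_per_mm["x"]))
  invisible(x)
}

#' Pixel scale of a calibrated acquisition
#'
#' The scale used to convert manual tracings from pixel to physical units:
#' a 320-pixel image spanning 3 mm gives 106.67 px/mm (reported at two
#' decimals; the full-precision value is used internally).
#'
#' @param image_px number of pixels along one axis (>= 1).
#' @param extent_mm physical length of that axis in mm (> 0).
#' @return Scale in pixels per millimetre, at full floating precision.
#' @examples
#' pixels_per_mm(320, 3)   # 106.6667
#' pixels_per_mm(100, 1)   # 100
#' @export
pixels_per_mm <- function(image_px, extent_mm) {
  if (!is.numeric(image_px) || length(image_px) != 1L || image_px < 1)
    stop("`image_px` must be a single value >= 1")
  if (!is.numeric(extent_mm) || length(extent_mm) != 1L ||
      !is.finite(extent_mm) || extent_mm <= 0)
    stop("`extent_mm` must be a single positive value")
  image_px / extent_mm
}

# Physical pixel size (mm) along x, from a calibrated image.
pixel_size_mm <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  1 / image$scale_px_per_mm[["x"]]
}

# Physical image area in mm^2.
image_area_mm2 <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  area <- image$extent_mm[["x"]] * image$extent_mm[["y"]]
  if (area <= 0) stop("image has zero physical area")
  area
}
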