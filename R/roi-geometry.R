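#' Traced polygon region of interest
#'
#' An ordered, implicitly closed vertex list in pixel coordinates, as produced
#' by manual outlining of the foveal avascular zone (FAZ) along the innermost
#' capillaries, or of the total choroidal area on a B-scan. Vertices are
#' continuous-valued (sub-pixel tracing is allowed); the polygon is measured
#' as a geometric polygon, not a rasterised mask.
#'
#' @param vertices two-column numeric matrix (or data frame) of `(x, y)`
#'   coordinates, at least 3 rows; the last vertex connects back to the first.
#' @return Object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stop("`vertices` must be a two-column numeric matrix of (x, y)")
  if (nrow(vertices) < 3L)
    stop("a polygon ROI needs at least 3 vertices")
  if (any(!is.finite(vertices)))
    stop("vertex coordinates must be finite")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices), class = "polygon_roi")
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi> %d vertices, area %.4g px^2\n",
              nrow(x$vertices), polygon_area_px2(x)))
  invisible(x)
}

# Signed shoelace area in px^2 (positive for counter-clockwise in a
# y-down coordinate system the sign is flipped; callers take abs()).
shoelace_signed <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area_px2 <- function(roi) abs(shoelace_signed(roi$vertices))

polygon_perimeter_px <- function(roi) {
  v <- roi$vertices
  vn <- v[c(2:nrow(v), 1L), , drop = FALSE]
  sum(sqrt(rowSums((vn - v)^2)))
}

#' Polygon area in physical units
#'
#' Shoelace area of the traced vertex polygon, converted from px^2 to mm^2.
#' Orientation-independent. With anisotropic pixels pass `scale` as
#' `c(scale_x, scale_y)`; area then uses `scale_x * scale_y`.
#'
#' @param roi a [polygon_roi()].
#' @param scale pixels per mm (one value, or two for anisotropic pixels).
#' @return Area in mm^2.
#' @examples
#' sq <- polygon_roi(rbind(c(0, 0), c(320, 0), c(320, 320), c(0, 320)))
#' polygon_area(sq, pixels_per_mm(320, 3))  # 9 mm^2
#' @export
polygon_area <- function(roi, scale) {
  stopifnot(inherits(roi, "polygon_roi"))
  scale <- check_scale(scale)
  a_px2 <- polygon_area_px2(roi)
  if (a_px2 == 0) stop("degenerate polygon: enclosed area is zero")
  a_px2 / (scale[1L] * scale[2L])
}

#' Polygon perimeter in physical units
#'
#' Sum of straight-segment edge lengths (including the closing edge),
#' converted to mm. No smoothing is applied to the traced outline.
#'
#' @inheritParams polygon_area
#' @return Perimeter in mm.
#' @export
polygon_perimeter <- function(roi, scale) {
  stopifnot(inherits(roi, "polygon_roi"))
  scale <- check_scale(scale)
  if (scale[1L] != scale[2L])
    stop("perimeter is only defined here for isotropic pixels")
  if (polygon_area_px2(roi) == 0)
    stop("degenerate polygon: enclosed area is zero")
  polygon_perimeter_px(roi) / scale[1L]
}

check_scale <- function(scale) {
  scale <- as.numeric(scale)
  if (length(scale) == 1L) scale <- c(scale, scale)
  if (length(scale) != 2L || any(!is.finite(scale)) || any(scale <= 0))
    stop("`scale` must be one or two positive px/mm values")
  scale
}

#' FAZ circularity index
#'
#' Isoperimetric compactness of a shape: `4 * pi * area / perimeter^2`.
#' A value of 1 is attained exactly by a circle; irregular, elongated
#' avascular zones score lower. No clipping is applied (a traced polygon can
#' exceed 1 only by discretisation error, bounded at about 0.01).
#'
#' @param area_mm2 enclosed area, mm^2 (> 0).
#' @param perimeter_mm boundary length, mm (> 0).
#' @return Dimensionless circularity index.
#' @examples
#' circularity_index(pi, 2 * pi)    # circle of radius 1 -> 1
#' circularity_index(0.52, 2.87)    # 0.79 (healthy deep-plexus means)
#' @export
circularity_index <- function(area_mm2, perimeter_mm) {
  if (!is.numeric(area_mm2) || !is.numeric(perimeter_mm))
    stop("inputs must be numeric")
  if (any(area_mm2 <= 0) || any(perimeter_mm <= 0))
    stop("area and perimeter must be positive")
  4 * pi * area_mm2 / perimeter_mm^2
}

#' FAZ morphometry from a traced outline
#'
#' Computes area (mm^2), perimeter (mm) and circularity index for a manually
#' traced FAZ polygon on a calibrated en-face image. Circularity is derived
#' from the exact (unrounded) area and perimeter.
#'
#' @param roi a [polygon_roi()] traced on `image`.
#' @param image a [calibrated_image()].
#' @return A list of class `faz_metrics`: `area_mm2`, `perimeter_mm`,
#'   `circularity`.
#' @examples
#' img <- calibrated_image(matrix(0, 320, 320), 3)
#' s <- img$scale_px_per_mm["x"]
#' sq <- polygon_roi(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
#' faz_metrics(sq, img)  # 1 mm^2, 4 mm, pi/4
#' @export
faz_metrics <- function(roi, image) {
  stopifnot(inherits(roi, "polygon_roi"), inherits(image, "calibrated_image"))
  v <- roi$vertices
  w <- ncol(image$pixels); h <- nrow(image$pixels)
  if (any(v[, 1L] < 0 | v[, 1L] > w | v[, 2L] < 0 | v[, 2L] > h))
    stop("ROI vertices fall outside the image bounds")
  sc <- image$scale_px_per_mm
  area <- polygon_area(roi, c(sc[["x"]], sc[["y"]]))
  perim <- polygon_perimeter(roi, sc[["x"]])
  structure(
    list(area_mm2 = area, perimeter_mm = perim,
         circularity = circularity_index(area, perim)),
    class = "faz_metrics"
  )
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf("FAZ area %.3f mm^2, perimeter %.3f mm, circularity %.3f\n",
              x$area_mm2, x$perimeter_mm, x$circularity))
  invisible(x)
}

#' Read / write a polygon ROI as JSON
#'
#' The interchange format is a small JSON object
#' `{"image": <name>, "layer": "SCP"|"DCP", "vertices": [[x, y], ...]}`;
#' `read_roi_csv()` additionally accepts a plain two-column vertex table.
#' ImageJ's binary `.roi` format is not supported.
#'
#' @param path file path.
#' @param roi a [polygon_roi()].
#' @param image_name,layer optional metadata stored alongside the vertices.
#' @return `read_roi_json()` returns a `polygon_roi` with attributes
#'   `image_name` and `layer`; `write_roi_json()` returns `path` invisibly.
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$vertices))
    stop(sprintf("ROI file '%s' has no 'vertices' field", path))
  roi <- polygon_roi(obj$vertices)
  attr(roi, "image_name") <- obj$image
  attr(roi, "layer") <- obj$layer
  roi
}

#' @rdname read_roi_json
#' @export
write_roi_json <- function(roi, path, image_name = NULL, layer = NULL) {
  stopifnot(inherits(roi, "polygon_roi"))
  obj <- list(image = image_name, layer = layer,
              vertices = unname(roi$vertices))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname read_roi_json
#' @export
read_roi_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L)
    stop(sprintf("ROI CSV '%s' must have two columns (x, y)", path))
  polygon_roi(as.matrix(tab[, 1:2]))
}
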