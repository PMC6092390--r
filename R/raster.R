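# Polygon rasterisation and clipping primitives shared by the FAZ and
# choroid quantification paths.

#' Rasterise a polygon ROI to a pixel mask
#'
#' A pixel belongs to the polygon iff its centre lies inside under the
#' even-odd rule. Pixel centres are at `(j - 0.5, i - 0.5)` for the matrix
#' entry `[i, j]` (see [calibrated_image()] for the coordinate convention).
#'
#' @param roi a [polygon_roi()].
#' @param dim_px image dimensions `c(nrow, ncol)`.
#' @return Logical matrix of the requested dimensions.
#' @export
rasterize_polygon <- function(roi, dim_px) {
  stopifnot(inherits(roi, "polygon_roi"), length(dim_px) == 2L)
  nr <- as.integer(dim_px[1L]); nc <- as.integer(dim_px[2L])
  v <- roi$vertices
  n <- nrow(v)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- v[c(2:n, 1L), 1L]; y2 <- v[c(2:n, 1L), 2L]
  mask <- matrix(FALSE, nr, nc)
  xc <- seq_len(nc) - 0.5
  for (i in seq_len(nr)) {
    yc <- i - 0.5
    # half-open rule [min, max) avoids double-counting shared vertices
    cross <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(cross)) next
    xs <- x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) /
      (y2[cross] - y1[cross])
    # even-odd: centre is inside iff an odd number of crossings lie left of it
    mask[i, ] <- (colSums(outer(xs, xc, `<`)) %% 2L) == 1L
  }
  mask
}

# Clip a polygon against the half-plane a*x + b*y <= c (Sutherland-Hodgman
# step). Returns a vertex matrix, possibly with zero rows.
clip_halfplane <- function(v, a, b, cc) {
  n <- nrow(v)
  if (n == 0L) return(v)
  out <- matrix(numeric(0), 0L, 2L)
  f <- a * v[, 1L] + b * v[, 2L] - cc   # <= 0 means inside
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- v[i, ]; q <- v[j, ]
    pin <- f[i] <= 0; qin <- f[j] <= 0
    if (pin) out <- rbind(out, p)
    if (pin != qin) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

#' Clip a polygon to a vertical pixel-column band
#'
#' Used to restrict a traced total-choroidal-area outline to the subfoveal
#' window. The band is `[x_lo, x_hi]` in continuous pixel coordinates.
#'
#' @param roi a [polygon_roi()].
#' @param x_lo,x_hi band limits in pixel coordinates, `x_lo < x_hi`.
#' @return The clipped [polygon_roi()].
#' @export
clip_polygon_x <- function(roi, x_lo, x_hi) {
  stopifnot(inherits(roi, "polygon_roi"), x_lo < x_hi)
  v <- roi$vertices
  v <- clip_halfplane(v, -1, 0, -x_lo)  # x >= x_lo
  v <- clip_halfplane(v, 1, 0, x_hi)    # x <= x_hi
  if (nrow(v) < 3L || abs(shoelace_signed(v)) == 0)
    stop("polygon does not overlap the window columns")
  polygon_roi(v)
}
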