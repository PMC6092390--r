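#' Niblack local-threshold parameters
#'
#' The Niblack auto local threshold classifies a pixel against a threshold
#' formed from the mean and standard deviation of its surrounding
#' `(2r+1) x (2r+1)` window: bright-foreground pixels satisfy
#' `intensity > mean + k * sd - c`; dark-foreground (used for choroidal
#' lumens) mirrors this as `intensity < mean - k * sd + c`. Local statistics
#' use mirror padding at the image border and the population (divide-by-n)
#' standard deviation.
#'
#' Defaults follow the common auto-local-threshold convention: radius 15 px,
#' `k = 0.2`, `c = 0`, bright foreground. All values are recorded in result
#' provenance.
#'
#' @param window_radius_px window radius `r` in pixels (>= 1).
#' @param k standard-deviation weight.
#' @param offset_c additive intensity offset `c`.
#' @param polarity `"bright"` (vessels on dark background) or `"dark"`
#'   (hyporeflective lumens on bright stroma).
#' @return Object of class `niblack_params`.
#' @export
niblack_params <- function(window_radius_px = 15L, k = 0.2, offset_c = 0,
                           polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  window_radius_px <- as.integer(window_radius_px)
  if (window_radius_px < 1L) stop("`window_radius_px` must be >= 1")
  if (!is.finite(k) || !is.finite(offset_c))
    stop("`k` and `offset_c` must be finite")
  structure(list(window_radius_px = window_radius_px, k = k,
                 offset_c = offset_c, polarity = polarity),
            class = "niblack_params")
}

# Mirror-pad a matrix by r on every side (border row/column repeated).
pad_mirror <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding radius exceeds image size")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  m[ri, ci, drop = FALSE]
}

# Windowed box sums of `m` over (2r+1)^2 neighbourhoods with mirror padding,
# via a summed-area table. Exact for integer-valued images (all partial sums
# are integers representable in double precision).
box_sums <- function(m, r) {
  p <- pad_mirror(m, r)
  # summed-area table with a zero first row/column
  s <- rbind(0, apply(p, 2L, cumsum))
  s <- cbind(0, t(apply(s, 1L, cumsum)))
  nr <- nrow(m); nc <- ncol(m)
  w <- 2L * r + 1L
  i1 <- seq_len(nr); i2 <- i1 + w
  j1 <- seq_len(nc); j2 <- j1 + w
  s[i2, j2] - s[i1, j2] - s[i2, j1] + s[i1, j1]
}

#' Binarize an image with the Niblack auto local threshold
#'
#' @param image a [calibrated_image()] or a plain numeric matrix.
#' @param params a [niblack_params()].
#' @return Logical matrix (foreground = `TRUE`), same shape as the image.
#' @examples
#' img <- matrix(c(30, 200)[1 + (matrix(runif(64 * 64), 64) > 0.7)], 64)
#' mask <- niblack_binarize(img, niblack_params(window_radius_px = 7))
#' @export
niblack_binarize <- function(image, params = niblack_params()) {
  stopifnot(inherits(params, "niblack_params"))
  m <- if (inherits(image, "calibrated_image")) image$pixels else image
  if (!is.matrix(m)) stop("`image` must be a matrix or calibrated_image")
  r <- params$window_radius_px
  if (2L * r + 1L > min(dim(m)))
    stop("Niblack window (2r+1) exceeds the smallest image side")
  n <- (2 * r + 1)^2
  s1 <- box_sums(m, r)
  s2 <- box_sums(m * m, r)
  mu <- s1 / n
  sd <- sqrt(pmax(s2 / n - mu * mu, 0))
  if (params$polarity == "bright") {
    m > mu + params$k * sd - params$offset_c
  } else {
    m < mu - params$k * sd + params$offset_c
  }
}
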