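# Shared fixtures: all built in code at test time.

# Regular n-gon approximating a circle, in pixel coordinates.
circle_roi <- function(radius_px, n = 256L, centre = c(160, 160)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  polygon_roi(cbind(centre[1L] + radius_px * cos(th),
                    centre[2L] + radius_px * sin(th)))
}

# Axis-aligned ellipse polygon.
ellipse_roi <- function(a_px, b_px, n = 512L, centre = c(160, 160)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  polygon_roi(cbind(centre[1L] + a_px * cos(th),
                    centre[2L] + b_px * sin(th)))
}

# Random convex polygon: convex hull of uniform points.
random_convex_roi <- function(n_pts = 12L, span = 100) {
  pts <- cbind(runif(n_pts, 0, span), runif(n_pts, 0, span))
  hull <- grDevices::chull(pts)
  polygon_roi(pts[hull, , drop = FALSE])
}

# Brute-force Niblack: direct windowed statistics, same padding and formulas.
niblack_naive <- function(m, params) {
  r <- params$window_radius_px
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(r:1, 1:nr, nr:(nr - r + 1)), c(r:1, 1:nc, nc:(nc - r + 1))]
  n <- (2 * r + 1)^2
  out <- matrix(NA, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    w <- pad[i:(i + 2 * r), j:(j + 2 * r)]
    s1 <- sum(w); s2 <- sum(w * w)
    mu <- s1 / n
    sd <- sqrt(max(s2 / n - mu * mu, 0))
    out[i, j] <- if (params$polarity == "bright")
      m[i, j] > mu + params$k * sd - params$offset_c
    else
      m[i, j] < mu - params$k * sd + params$offset_c
  }
  out
}

# Brute-force DeLong structural components (x = diseased, y = healthy).
delong_naive <- function(x, y) {
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  list(auc = mean(v10), var = var(v10) / m + var(v01) / n)
}

# Tie-corrected Mann-Whitney AUC via midranks.
mw_auc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Exhaustive Youden search over midpoint thresholds on the oriented scale.
youden_naive <- function(scores, labels) {
  labels <- as.logical(labels)
  flip <- mw_auc(scores[labels], scores[!labels]) < 0.5
  s <- if (flip) -scores else scores
  sv <- sort(unique(s))
  cand <- c(sv[1] - 1, (head(sv, -1) + tail(sv, -1)) / 2, sv[length(sv)] + 1)
  best_j <- -Inf
  for (t in cand) {
    pred <- s >= t
    j <- sum(pred & labels) / sum(labels) +
      sum(!pred & !labels) / sum(!labels) - 1
    if (j > best_j + 1e-12) best_j <- j
  }
  best_j
}
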