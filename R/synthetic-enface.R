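# Synthetic en-face OCT angiography phantoms with known ground truth.
#
# The vessel network is grown by biased random walkers seeded on the image
# edges (branching with fixed probability) and dilated to the requested
# thickness, which yields a true centreline pixel set and hence a known
# skeleton length. The avascular zone boundary is a truncated Fourier radial
# perturbation of a circle, giving analytic control of area, perimeter and
# circularity.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Specification of an en-face phantom
#'
#' Defaults emulate a 3 x 3 mm, 320 x 320 px macular angiogram: a central
#' avascular zone of mean radius 0.36 mm (area close to 0.40 mm^2, the
#' healthy superficial-plexus value), a capillary network occupying about a
#' third of the scan, vessels around 3 px (28 um) thick, and 8-bit
#' intensities with vessels at 200 on a background of 30.
#'
#' @param image_px pixels per side (>= 32).
#' @param extent_mm physical side length, mm.
#' @param faz_mean_radius mean avascular-zone radius, mm
#'   (< `extent_mm / 2`).
#' @param faz_harmonic_amps radial perturbation amplitudes (mm) of the
#'   Fourier harmonics k = 2, 3, ... controlling contour irregularity.
#' @param vessel_fraction_target target foreground fraction in `[0, 1)`.
#' @param vessel_width_px mean vessel thickness, px.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param seed integer RNG seed.
#' @return Object of class `enface_phantom_spec`.
#' @export
enface_phantom_spec <- function(image_px = 320L, extent_mm = 3,
                                faz_mean_radius = 0.36,
                                faz_harmonic_amps = c(0.04, 0.03),
                                vessel_fraction_target = 0.35,
                                vessel_width_px = 3L,
                                noise_sd = 10, seed = 1L) {
  image_px <- as.integer(image_px)
  if (image_px < 32L) stop("`image_px` must be >= 32")
  if (extent_mm <= 0) stop("`extent_mm` must be positive")
  if (vessel_fraction_target < 0 || vessel_fraction_target >= 1)
    stop("`vessel_fraction_target` must be in [0, 1)")
  if (faz_mean_radius >= extent_mm / 2)
    stop("`faz_mean_radius` must be smaller than half the extent")
  if (faz_mean_radius < 0 || any(faz_harmonic_amps < 0))
    stop("radius and harmonic amplitudes must be non-negative")
  if (sum(faz_harmonic_amps) >= faz_mean_radius && faz_mean_radius > 0)
    stop("harmonic amplitudes would make the contour self-intersecting")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(
    list(image_px = image_px, extent_mm = extent_mm,
         faz_mean_radius = faz_mean_radius,
         faz_harmonic_amps = faz_harmonic_amps,
         vessel_fraction_target = vessel_fraction_target,
         vessel_width_px = as.integer(vessel_width_px),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "enface_phantom_spec"
  )
}

# Fourier-perturbed closed contour r(theta) = r0 + sum_k a_k cos(k theta +
# phi_k), harmonics starting at k = 2 so the centroid stays put.
faz_contour <- function(r0_px, amps_px, phases, n_vertices, centre) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(r0_px, n_vertices)
  for (i in seq_along(amps_px))
    r <- r + amps_px[i] * cos((i + 1L) * th + phases[i])
  polygon_roi(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)))
}

# Binary dilation by a disk of the given radius (offsets with dx^2+dy^2<=r^2).
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  out <- mask
  for (dx in -radius:radius) for (dy in -radius:radius) {
    if (dx == 0 && dy == 0) next
    if (dx * dx + dy * dy <= radius * radius + 1e-9)
      out <- out | shift_mat(mask * 1L, dy, dx) > 0L
  }
  out
}

# Grow one branching walker; returns linear pixel indices of its path.
# Walkers are anastomotic: on entering the join zone around an existing
# vessel centreline the walker joins it and terminates (capillaries join
# rather than overlap), so no two centrelines run closer than the vessel
# thickness and the centreline length stays a recoverable ground truth.
# Branches get a short grace period so they can leave their parent before
# the join rule applies.
walk_vessel <- function(npx, join_zone, seed_idx, max_steps, turn_sd,
                        branch_prob) {
  path <- integer(0)
  # seed at the centre of a free pixel, heading in a random direction
  iy <- (seed_idx - 1L) %% npx + 1L
  ix <- (seed_idx - 1L) %/% npx + 1L
  pos <- c(ix - 0.5, iy - 0.5)
  dir <- stats::runif(1, 0, 2 * pi)
  stack <- list(list(pos = pos, dir = dir, grace = 2L))
  steps <- 0L
  while (length(stack) > 0L && steps < max_steps) {
    w <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    pos <- w$pos; dir <- w$dir; grace <- w$grace
    repeat {
      steps <- steps + 1L
      pos <- pos + c(cos(dir), sin(dir))
      if (pos[1L] < 0 || pos[1L] >= npx || pos[2L] < 0 || pos[2L] >= npx ||
          steps >= max_steps) break
      ix <- floor(pos[1L]) + 1L; iy <- floor(pos[2L]) + 1L
      idx <- (ix - 1L) * npx + iy
      if (grace <= 0L && join_zone[idx]) {
        path <- c(path, idx)  # join the met vessel, then stop
        break
      }
      grace <- grace - 1L
      path <- c(path, idx)
      dir <- dir + stats::rnorm(1L, 0, turn_sd)
      if (stats::runif(1L) < branch_prob && length(stack) < 24L)
        stack[[length(stack) + 1L]] <-
          list(pos = pos,
               dir = dir + sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1.1),
               grace = 8L)
    }
  }
  path
}

#' Generate an en-face OCT angiography phantom
#'
#' Deterministic for a fixed seed. The returned ground truth is recomputed
#' from the generated rasters: `truth_vessel_fraction` is the exact
#' foreground fraction of `truth_vessel_mask`, and `truth_skeleton_length_mm`
#' is the count of distinct centreline pixels times the pixel size (the same
#' pixel-counting length convention used by [vessel_length_density()]).
#'
#' @param spec an [enface_phantom_spec()].
#' @return Object of class `enface_phantom`: `image` ([calibrated_image()]),
#'   `truth_vessel_mask`, `truth_faz_polygon`, `truth_vessel_fraction`,
#'   `truth_skeleton_length_mm`, `spec`.
#' @export
generate_enface_phantom <- function(spec) {
  stopifnot(inherits(spec, "enface_phantom_spec"))
  with_seed(spec$seed, {
    npx <- spec$image_px
    scale <- npx / spec$extent_mm
    centre <- c(npx, npx) / 2
    phases <- stats::runif(length(spec$faz_harmonic_amps), 0, 2 * pi)
    faz <- faz_contour(spec$faz_mean_radius * scale,
                       spec$faz_harmonic_amps * scale,
                       phases, 256L, centre)
    faz_raster <- if (spec$faz_mean_radius > 0)
      rasterize_polygon(faz, c(npx, npx)) else matrix(FALSE, npx, npx)

    target <- spec$vessel_fraction_target
    avail <- 1 - sum(faz_raster) / npx^2
    if (target > 0.9 * avail)
      stop("vessel_fraction_target is unreachable for this geometry")

    centreline <- matrix(FALSE, npx, npx)
    mask <- matrix(FALSE, npx, npx)
    join_zone <- matrix(FALSE, npx, npx)
    dil_r <- max(0L, (spec$vessel_width_px - 1L) %/% 2L)
    # disk offsets used for incremental dilation of new path pixels
    disk_offsets <- function(radius) {
      o <- expand.grid(dy = -radius:radius, dx = -radius:radius)
      o[o$dy^2 + o$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
    }
    stamp <- function(canvas, idx, offsets) {
      iy <- (idx - 1L) %% npx + 1L
      ix <- (idx - 1L) %/% npx + 1L
      for (k in seq_len(nrow(offsets))) {
        y <- iy + offsets$dy[k]; x <- ix + offsets$dx[k]
        ok <- y >= 1L & y <= npx & x >= 1L & x <= npx
        canvas[(x[ok] - 1L) * npx + y[ok]] <- TRUE
      }
      canvas
    }
    join_zone <- join_zone | faz_raster
    if (target > 0) {
      off_mask <- disk_offsets(dil_r)
      off_join <- disk_offsets(dil_r + 1L)
      walkers <- 0L
      n_target <- target * npx^2
      repeat {
        free <- which(!join_zone)
        if (!length(free))
          stop("vessel_fraction_target is unreachable for this geometry")
        idx <- walk_vessel(npx, join_zone, free[sample.int(length(free), 1L)],
                           max_steps = 4L * npx,
                           turn_sd = 0.08, branch_prob = 0.02)
        walkers <- walkers + 1L
        if (length(idx)) {
          idx <- unique(idx)
          centreline[idx] <- TRUE
          mask <- stamp(mask, idx, off_mask)
          join_zone <- stamp(join_zone, idx, off_join)
        }
        if (sum(mask & !faz_raster) >= n_target) break
        if (walkers > 20000L)
          stop("vessel_fraction_target is unreachable for this geometry")
      }
      mask[faz_raster] <- FALSE
      centreline[faz_raster] <- FALSE
      centreline <- centreline & mask
    }

    img <- matrix(30, npx, npx)
    img[mask] <- 200
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(npx^2, 0, spec$noise_sd)
    img <- round(pmin(pmax(img, 0), 255))

    frac <- sum(mask) / npx^2
    if (target > 0 && abs(frac - target) / target > 0.2)
      stop("achieved vessel fraction deviates more than 20% from target")

    structure(
      list(image = calibrated_image(img, spec$extent_mm),
           truth_vessel_mask = mask,
           truth_centreline = centreline,
           truth_faz_polygon = faz,
           truth_vessel_fraction = frac,
           truth_skeleton_length_mm = sum(centreline) / scale,
           spec = spec),
      class = "enface_phantom"
    )
  })
}
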