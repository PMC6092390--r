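# Choroidal vascularity index (CVI) on a subfoveal B-scan window:
# CVI = luminal area / total choroidal area, in percent.

#' Subfoveal measurement window
#'
#' The CVI is measured within a fixed lateral band centred on the fovea:
#' 750 um on either side, i.e. 1,500 um total width. The foveal column is an
#' input (the foveal raster scan is selected manually); the lateral
#' micrometre-per-pixel calibration is device-specific and must always be
#' supplied.
#'
#' @param fovea_x_px lateral pixel position of the fovea (continuous allowed).
#' @param lateral_scale_um_per_px lateral calibration, um per pixel (> 0).
#' @param half_width_um half-width of the band in um (default 750).
#' @return Object of class `subfoveal_window` with the derived column range
#'   `x_lo`, `x_hi` in pixel coordinates.
#' @export
subfoveal_window <- function(fovea_x_px, lateral_scale_um_per_px,
                             half_width_um = 750) {
  if (missing(lateral_scale_um_per_px))
    stop("`lateral_scale_um_per_px` is required (device-specific, no default)")
  stopifnot(is.numeric(fovea_x_px), length(fovea_x_px) == 1L,
            is.numeric(lateral_scale_um_per_px),
            lateral_scale_um_per_px > 0, half_width_um > 0)
  hw_px <- half_width_um / lateral_scale_um_per_px
  structure(
    list(fovea_x_px = fovea_x_px,
         lateral_scale_um_per_px = lateral_scale_um_per_px,
         half_width_um = half_width_um,
         x_lo = fovea_x_px - hw_px, x_hi = fovea_x_px + hw_px),
    class = "subfoveal_window"
  )
}

#' Clip a total-choroidal-area polygon to the subfoveal window
#'
#' @param tca a [polygon_roi()] tracing the total choroidal area.
#' @param window a [subfoveal_window()].
#' @return The clipped [polygon_roi()]; errors if the polygon does not
#'   overlap the window columns.
#' @export
clip_to_window <- function(tca, window) {
  stopifnot(inherits(tca, "polygon_roi"), inherits(window, "subfoveal_window"))
  clip_polygon_x(tca, window$x_lo, window$x_hi)
}

#' Luminal mask within the choroidal ROI
#'
#' Applies a dark-foreground Niblack local threshold to the (8-bit) B-scan
#' and intersects the resulting dark-pixel mask with the rasterised TCA
#' polygon — the "AND" step of the Agrawal binarization protocol. Dark pixels
#' are hyporeflective vessel lumens; bright stroma is excluded.
#'
#' @param image a [calibrated_image()] B-scan (intensities 0-255).
#' @param tca a [polygon_roi()] (already clipped to the window if desired).
#' @param params a [niblack_params()] with `polarity = "dark"`.
#' @return Logical matrix: lumen pixels inside the TCA.
#' @export
luminal_mask <- function(image, tca,
                         params = niblack_params(polarity = "dark")) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(tca, "polygon_roi"),
            inherits(params, "niblack_params"))
  if (params$polarity != "dark")
    stop("luminal segmentation requires dark-foreground polarity")
  tca_px <- rasterize_polygon(tca, dim(image$pixels))
  if (!any(tca_px)) stop("rasterised TCA polygon is empty")
  niblack_binarize(image, params) & tca_px
}

#' Compute the choroidal vascularity index
#'
#' Clips the TCA outline to the subfoveal window, segments the luminal area,
#' and reports CVI = 100 * LA / TCA (pixel counts), plus areas in mm^2 when
#' the axial calibration is known.
#'
#' @inheritParams luminal_mask
#' @param window a [subfoveal_window()].
#' @param axial_scale_um_per_px optional axial calibration for mm^2 areas.
#' @return Object of class `cvi_result`: `tca_px`, `la_px`, `cvi_pct`, and
#'   optionally `tca_mm2`, `la_mm2`.
#' @export
compute_cvi <- function(image, tca, window,
                        params = niblack_params(polarity = "dark"),
                        axial_scale_um_per_px = NULL) {
  stopifnot(inherits(window, "subfoveal_window"))
  tca_win <- clip_to_window(tca, window)
  tca_raster <- rasterize_polygon(tca_win, dim(image$pixels))
  n_tca <- sum(tca_raster)
  if (n_tca == 0L) stop("rasterised TCA polygon is empty within the window")
  la <- luminal_mask(image, tca_win, params)
  n_la <- sum(la)
  px_mm2 <- NULL
  if (!is.null(axial_scale_um_per_px))
    px_mm2 <- (window$lateral_scale_um_per_px / 1000) *
      (axial_scale_um_per_px / 1000)
  structure(
    list(tca_px = n_tca, la_px = n_la,
         tca_mm2 = if (!is.null(px_mm2)) n_tca * px_mm2,
         la_mm2 = if (!is.null(px_mm2)) n_la * px_mm2,
         cvi_pct = 100 * n_la / n_tca,
         params = params, window = window),
    class = "cvi_result"
  )
}

#' @export
print.cvi_result <- function(x, ...) {
  cat(sprintf("CVI %.2f%% (LA %d px / TCA %d px)\n",
              x$cvi_pct, x$la_px, x$tca_px))
  invisible(x)
}
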