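# End-to-end orchestration and file I/O: images (PNG/TIFF, 8-bit grayscale),
# masks, ROI JSON, cohort CSV, and a reproducible run manifest.

#' Read a grayscale image as a calibrated image
#'
#' PNG and TIFF are supported; colour images are reduced to the first
#' channel. 16-bit TIFF input is rescaled to the 8-bit range with a note.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param extent_mm physical extent passed to [calibrated_image()].
#' @return A [calibrated_image()] with intensities in 0-255.
#' @export
read_image <- function(path, extent_mm) {
  if (!file.exists(path)) stop(sprintf("image file '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    m <- round(a * 255)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    if (max(a) > 255) {
      message(sprintf("'%s': 16-bit input rescaled to 8-bit", path))
      a <- a * 255 / 65535
    }
    m <- round(a)
  } else {
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext))
  }
  calibrated_image(m, extent_mm)
}

#' Write an 8-bit grayscale image or a binary mask as PNG
#'
#' `write_image()` writes intensities 0-255; `write_mask()` writes a logical
#' mask as 0/255 so that `read_mask()` round-trips it exactly.
#'
#' @param image a [calibrated_image()] or numeric matrix (0-255).
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  m <- if (inherits(image, "calibrated_image")) image$pixels else image
  png::writePNG(pmin(pmax(m, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0.5
}

cohort_required_cols <- c("eye_id", "patient_id", "group", "age", "sex",
                          "dbp", "ssi")

#' Read / write a cohort CSV
#'
#' The schema is one row per eye: `eye_id, patient_id, group (1-6), age,
#' sex, dbp, ssi`, followed by one column per metric. Schema violations are
#' reported with the offending column or value.
#'
#' @param path CSV path.
#' @param cohort cohort data frame.
#' @return `read_cohort_csv()` returns the validated data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort file '%s' not found", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_cols, names(tab))
  if (length(missing))
    stop(sprintf("cohort '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(tab$eye_id))
    stop(sprintf("cohort '%s' has duplicated eye_id values", path))
  if (!all(tab$group %in% 1:6))
    stop(sprintf("cohort '%s': `group` must be in 1..6", path))
  tab
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  missing <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing))
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Run the full quantification and statistics pipeline
#'
#' Orchestrates the analysis sequence over a prepared set of inputs: reads
#' and quality-filters the cohort table, quantifies any en-face images
#' present (Niblack binarization, vessel density, skeleton length density,
#' FAZ morphometry from a traced outline), fits covariate-adjusted severity
#' trends, evaluates both diagnostic contrasts, writes all tables under
#' `config$out_dir`, and returns a manifest with a config snapshot and
#' output hashes. Eyes listed in the cohort whose image or ROI file is
#' missing are recorded in an exclusion report, never skipped silently.
#'
#' @param config a list:
#'   \describe{
#'     \item{cohort_csv}{path to the cohort table (required).}
#'     \item{out_dir}{output directory (required).}
#'     \item{images_dir}{optional directory with `<eye_id>.png` en-face
#'       images and `<eye_id>_faz.json` traced outlines.}
#'     \item{extent_mm}{en-face physical extent (default 3).}
#'     \item{enface_niblack}{list of [niblack_params()] arguments for the
#'       en-face stage.}
#'     \item{ssi_min}{quality threshold (default 60).}
#'     \item{metrics}{metric columns for the statistics stage (default: all
#'       metric columns in the cohort).}
#'     \item{trend_groups}{groups used in the trend fit (default 1:6).}
#'     \item{seed}{recorded in the manifest.}
#'   }
#' @return The manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  for (f in c("cohort_csv", "out_dir"))
    if (is.null(config[[f]])) stop(sprintf("config$%s is required", f))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))

  cohort <- read_cohort_csv(config$cohort_csv)
  n0 <- nrow(cohort)
  ssi_min <- config$ssi_min %||% 60
  cohort <- filter_quality(cohort, ssi_min)
  log_msg("[quality] %d eyes in, %d removed (ssi <= %g), %d retained",
          n0, attr(cohort, "n_removed"), ssi_min, nrow(cohort))
  if (nrow(cohort) == 0L)
    stop("empty cohort after quality filtering")

  exclusions <- data.frame(eye_id = character(0), reason = character(0))
  if (!is.null(config$images_dir)) {
    extent <- config$extent_mm %||% 3
    np <- do.call(niblack_params, config$enface_niblack %||% list())
    meas <- data.frame(eye_id = cohort$eye_id,
                       vd_measured = NA_real_, vld_measured = NA_real_,
                       faz_area_measured = NA_real_,
                       faz_perim_measured = NA_real_,
                       faz_circ_measured = NA_real_)
    for (i in seq_len(nrow(cohort))) {
      id <- cohort$eye_id[i]
      img_path <- file.path(config$images_dir, paste0(id, ".png"))
      if (!file.exists(img_path)) {
        exclusions <- rbind(exclusions,
                            data.frame(eye_id = id, reason = "missing image"))
        next
      }
      img <- read_image(img_path, extent)
      q <- quantify_enface(img, np)
      meas$vd_measured[i] <- q$vessel_density_pct
      meas$vld_measured[i] <- q$vessel_length_density_mm_inv
      roi_path <- file.path(config$images_dir, paste0(id, "_faz.json"))
      if (file.exists(roi_path)) {
        fm <- faz_metrics(read_roi_json(roi_path), img)
        meas$faz_area_measured[i] <- fm$area_mm2
        meas$faz_perim_measured[i] <- fm$perimeter_mm
        meas$faz_circ_measured[i] <- fm$circularity
      } else {
        exclusions <- rbind(exclusions,
                            data.frame(eye_id = id,
                                       reason = "missing FAZ ROI"))
      }
    }
    cohort <- merge(cohort, meas, by = "eye_id", sort = FALSE)
    log_msg("[images] %d eyes quantified, %d exclusions",
            sum(!is.na(meas$vd_measured)), nrow(exclusions))
  }

  metrics <- config$metrics %||%
    setdiff(names(cohort), cohort_required_cols)
  metrics <- metrics[vapply(metrics, function(m)
    is.numeric(cohort[[m]]) && sum(!is.na(cohort[[m]])) > 0, logical(1))]

  files <- character(0)
  eyes_csv <- file.path(config$out_dir, "eyes.csv")
  write_cohort_csv(cohort, eyes_csv)
  files <- c(files, eyes_csv)

  trends <- trend_table(cohort, metrics,
                        groups = config$trend_groups %||% 1:6)
  trends_csv <- file.path(config$out_dir, "trends.csv")
  utils::write.csv(trends, trends_csv, row.names = FALSE)
  files <- c(files, trends_csv)
  log_msg("[trends] %d metrics fitted", nrow(trends))

  diag_rows <- list()
  for (ct in c("noDR_vs_DR", "early_vs_advanced")) for (m in metrics) {
    row <- tryCatch(diagnostic_summary(cohort, m, ct),
                    error = function(e) {
                      log_msg("[diagnostics] %s / %s skipped: %s",
                              m, ct, conditionMessage(e))
                      NULL
                    })
    if (!is.null(row)) diag_rows[[length(diag_rows) + 1L]] <- row
  }
  diag <- do.call(rbind, diag_rows)
  diag_csv <- file.path(config$out_dir, "diagnostics.csv")
  utils::write.csv(diag, diag_csv, row.names = FALSE)
  files <- c(files, diag_csv)
  log_msg("[diagnostics] %d metric x contrast rows", nrow(diag))

  if (nrow(exclusions)) {
    excl_csv <- file.path(config$out_dir, "exclusions.csv")
    utils::write.csv(exclusions, excl_csv, row.names = FALSE)
    files <- c(files, excl_csv)
  }

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("octaquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
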