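#!/usr/bin/env Rscript
# Stage 2 — quantify the phantom images and confront every estimate with its
# generator ground truth.
#
# Reads results/phantoms/ from stage 1, runs FAZ morphometry on the traced
# avascular-zone outlines, Niblack binarization + skeletonization on the
# en-face images, and the CVI chain on the choroid window. Writes
# results/quantification.csv.

library(octaquant)

out_dir <- "results/phantoms"
if (!dir.exists(out_dir)) stop("run analysis/01_generate_phantoms.R first")

rows <- list()
cat("== en-face quantification (radius 15 px, k = 0.2, c = 0) ==\n")
for (f in list.files(out_dir, pattern = "^enface_.*[0-9]\\.png$")) {
  stem <- sub("\\.png$", "", f)
  img <- read_image(file.path(out_dir, f), extent_mm = 3)
  truth <- jsonlite::fromJSON(file.path(out_dir, paste0(stem, "_truth.json")))
  q <- quantify_enface(img)
  fm <- faz_metrics(read_roi_json(file.path(out_dir, paste0(stem, "_faz.json"))),
                    img)
  vld_truth <- truth$truth_skeleton_length_mm / 9
  rows[[stem]] <- data.frame(
    image = f,
    vd_true = 100 * truth$truth_vessel_fraction,
    vd_est = q$vessel_density_pct,
    vld_true = vld_truth,
    vld_est = q$vessel_length_density_mm_inv,
    faz_area = fm$area_mm2, faz_perim = fm$perimeter_mm,
    faz_circ = fm$circularity)
  cat(sprintf("  %s: VD %.2f%% (true %.2f), VLD %.3f /mm (true %.3f), FAZ CI %.3f\n",
              stem, q$vessel_density_pct, 100 * truth$truth_vessel_fraction,
              q$vessel_length_density_mm_inv, vld_truth, fm$circularity))
}

cat("== choroidal vascularity index ==\n")
img <- read_image(file.path(out_dir, "choroid.png"),
                  extent_mm = c(216, 120) * 7 / 1000)
tca <- read_roi_json(file.path(out_dir, "choroid_tca.json"))
w <- subfoveal_window(fovea_x_px = 108, lateral_scale_um_per_px = 7)
cv <- compute_cvi(img, tca, w)
cat(sprintf("  CVI %.2f%% (LA %d px / TCA %d px)\n",
            cv$cvi_pct, cv$la_px, cv$tca_px))

tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/quantification.csv", row.names = FALSE)
cat("wrote results/quantification.csv\n")
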