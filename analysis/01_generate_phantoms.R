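#!/usr/bin/env Rscript
# Stage 1 — synthesize the study inputs.
#
# Generates en-face angiogram phantoms at three vessel-density levels, a
# subfoveal choroid phantom, and the 174-eye six-group reference cohort.
# Images go to results/phantoms/ (PNG + sidecar truth JSON), the cohort to
# results/cohort.csv. Re-running with the same seed reproduces every byte.

library(octaquant)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out_dir <- "results/phantoms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat("== en-face phantoms (320 px / 3 mm, noiseless + noisy) ==\n")
for (tgt in c(0.15, 0.25, 0.35)) {
  for (noise in c(0, 10)) {
    spec <- enface_phantom_spec(vessel_fraction_target = tgt,
                                noise_sd = noise, seed = seed)
    ph <- generate_enface_phantom(spec)
    stem <- sprintf("enface_vf%02d_n%02d", round(100 * tgt), noise)
    write_image(ph$image, file.path(out_dir, paste0(stem, ".png")))
    write_mask(ph$truth_vessel_mask,
               file.path(out_dir, paste0(stem, "_mask.png")))
    write_roi_json(ph$truth_faz_polygon,
                   file.path(out_dir, paste0(stem, "_faz.json")),
                   image_name = paste0(stem, ".png"), layer = "SCP")
    jsonlite::write_json(
      list(spec = unclass(spec),
           truth_vessel_fraction = ph$truth_vessel_fraction,
           truth_skeleton_length_mm = ph$truth_skeleton_length_mm),
      file.path(out_dir, paste0(stem, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
    cat(sprintf("  %s: achieved fraction %.4f, centreline %.1f mm\n",
                stem, ph$truth_vessel_fraction, ph$truth_skeleton_length_mm))
  }
}

cat("== choroid phantom (subfoveal window, 69% luminal) ==\n")
ch <- generate_choroid_phantom(choroid_phantom_spec(seed = seed))
write_image(ch$image, file.path(out_dir, "choroid.png"))
write_mask(ch$truth_luminal_mask, file.path(out_dir, "choroid_lumen.png"))
write_roi_json(ch$tca_polygon, file.path(out_dir, "choroid_tca.json"))
cat(sprintf("  achieved luminal fraction %.4f\n", ch$truth_luminal_fraction))

cat("== reference cohort (six DR severity groups) ==\n")
coh <- generate_cohort(cohort_spec(seed = seed))
write_cohort_csv(coh, "results/cohort.csv")
cat(sprintf("  %d eyes, %d patients; group sizes: %s\n",
            nrow(coh), length(unique(coh$patient_id)),
            paste(table(coh$group), collapse = "/")))
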