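---
title: "Quantifying retinal and choroidal vasculature across diabetic retinopathy stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal and choroidal vasculature across diabetic retinopathy stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## What the package computes

Diabetic retinopathy (DR) progressively remodels the retinal capillary bed
and the choroid. `octaquant` implements the standard quantitative read-outs
used to track that remodelling on swept-source OCT angiography and OCT
B-scans, together with the cohort-level statistics used to relate them to DR
severity:

* **FAZ morphometry.** The foveal avascular zone is traced manually as a
  polygon on a 3 mm x 3 mm, 320 x 320 px en-face angiogram (106.67 px/mm).
  Area `A` (shoelace formula), perimeter `P` (straight segments), and the
  circularity index `CI = 4 * pi * A / P^2` are computed from the geometric
  polygon. `CI = 1` for a circle; irregular, eroded avascular zones score
  lower.
* **Vessel density (VD).** The angiogram is binarized with a Niblack auto
  local threshold (pixel is vessel iff `I > mean + k * sd - c` over a
  `(2r+1)^2` window); VD is the foreground percentage of the measured
  region.
* **Vessel length density (VLD).** The binary mask is thinned to 1-px
  centrelines (Zhang-Suen) and VLD = (skeleton pixels x pixel size) / image
  area, in 1/mm.
* **Choroidal vascularity index (CVI).** On a subfoveal B-scan window
  (750 um on either side of the fovea, 1,500 um total), the traced total
  choroidal area (TCA) polygon is clipped to the window, dark (hyporeflective,
  luminal) pixels are segmented with a dark-polarity Niblack threshold and
  intersected with the TCA raster; CVI = 100 * LA / TCA.
* **Cohort statistics.** Eyes are filtered at signal strength index > 60
  (strict). Severity trends are linear mixed models
  `metric ~ severity + age + sex + dbp + (1 | patient)` with the six-level
  ordinal group code (healthy, no DR, mild/moderate/severe NPDR, PDR)
  treated as numeric, so each metric gets one adjusted slope per severity
  step with a Wald two-tailed p-value. Diagnostic ability uses ROC curves
  with DeLong AUC confidence intervals and Youden-index cutoffs with Wilson
  score intervals for sensitivity and specificity.

Because no clinical images ship with the package, a synthetic-data module
generates all three input kinds with known ground truth; every downstream
stage is validated against that truth in the test suite.

## The synthetic generators and what they emulate

### En-face phantoms

`generate_enface_phantom()` grows a capillary-like network from biased
random walkers: each walker starts at a random free pixel with a random
heading, takes unit-length steps with small Gaussian heading changes
(SD 0.08 rad/step), branches with probability 0.02 per step, and
*anastomoses* — it terminates by joining any vessel it approaches within the
vessel thickness. The recorded centreline pixels are dilated to the requested
vessel width (default 3 px, about 28 um). This model was chosen over
band-pass noise textures precisely because it yields a true centreline: the
generator reports `truth_skeleton_length_mm` as the count of distinct
centreline pixels times the pixel size, the same pixel-counting convention
the estimator uses, so skeleton-length recovery is a meaningful end-to-end
check. The anastomosis rule matters: without it, walkers can run parallel
within one vessel width, the dilated corridors merge, and the "true" length
is not recoverable even in principle.

The avascular zone is a truncated Fourier contour
`r(theta) = r0 + sum_k a_k cos(k * theta + phi_k)` (harmonics from k = 2, so
the centroid stays put), sampled at 256 vertices. Amplitudes of zero give a
circle (circularity -> 1 as the vertex count grows); growing amplitudes give
monotonically decreasing circularity, which the tests exploit. Default mean
radius 0.36 mm gives an area near 0.40 mm^2, a typical healthy superficial
plexus value.

Intensities are 8-bit: vessels at 200, background at 30, optional Gaussian
noise (default SD 10) clipped to [0, 255]. The target vessel fraction is a
*target*: generation stops once the achieved fraction reaches it, the truth
field is recomputed from the final mask, and the generator errors if the
achieved fraction misses the target by more than 20% relative or if the
geometry cannot reach it at all.

What the phantoms do **not** emulate: OCT speckle, projection and motion
artifacts, capillary dropout morphology, layer-segmentation errors, and the
graded intensity of real flow signal. Passing recovery tests therefore shows
the *measurement chain* is correct, not that any particular clinical value
would be reproduced on real scans.

### Choroid phantoms

`generate_choroid_phantom()` fills a rectangular TCA polygon (default
120 x 216 px at 7 um/px laterally, i.e. a window slightly wider than
1,500 um) with dark elliptical lumens (radius ~6 px) on bright stroma
(200 vs 30), adding blobs until the dark fraction inside the TCA reaches the
target; the final blobs are shrunk to the remaining deficit, so the achieved
fraction lands within 0.02 of the target and is re-measured from the mask.
The default 69% luminal fraction mirrors a healthy-control CVI.

### Cohorts

`generate_cohort()` draws one row per eye in six severity groups. Each
metric is `group mean + patient intercept + residual`; the patient intercept
(default SD: half the smallest group SD of that metric) is shared by both
eyes of bilateral patients (default 60% of patients), and the residual SD is
scaled so the *total* SD matches the group SD. The bundled reference
parameterization (`dr_reference_params()`) encodes the group sizes
(42/30/22/23/42/15 eyes, 174 total) and per-group means/SDs of all eleven
metrics, plus age, sex and diastolic-BP summaries per group. Healthy-control
diastolic BP is not part of the reference summaries and defaults to a
normotensive 75 +/- 9 mmHg. Signal strength index is drawn at 75 +/- 8 so a
realistic few percent of eyes fail the > 60 quality gate.

Two deliberate simplifications, relevant when interpreting test results:
metrics are generated independently of each other and of the covariates
(sufficient to validate the trend/ROC machinery, but it means cross-metric
correlations and confounding structure of real cohorts are absent), and the
severe-NPDR deep-plexus perimeter SD is kept at its reference value of 0.06
even though it is suspiciously small next to the other perimeter SDs.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| Niblack window radius | 15 | px | ~0.14 mm context window; standard auto-local-threshold scale for 320-px macular scans |
| Niblack `k` | 0.2 | — | common default weight; raising `k` strictly shrinks bright foreground |
| Niblack offset `c` | 0 | intensity | kept for protocol compatibility |
| polarity | bright (en-face), dark (choroid) | — | vessels are hyperreflective in angiograms; lumens hyporeflective in B-scans |
| `ssi_min` | 60 | — | strict `> 60` quality gate |
| subfoveal half-width | 750 | um | 1,500-um window total |
| lateral B-scan scale | none | um/px | device-specific; deliberately has no default |
| vessel width | 3 | px | ~28 um, capillary scale at 106.67 px/mm |

All thresholds live in configuration (`niblack_params()`, `run_pipeline()`
config) and are recorded in result provenance; nothing is hard-coded.

## Numerical choices

* **Local statistics** use mirror padding at the borders and the population
  (divide-by-n) variance; with integer-valued 8-bit images the summed-area
  implementation is *exactly* equal to direct windowed sums, which the tests
  assert bit-for-bit against a naive double loop.
* **Dark polarity** is the mirror of the bright rule
  (`I < mean - k * sd + c`), so a constant window is never foreground under
  either polarity; a one-sided reading of the threshold would classify
  uniform regions as lumen.
* **Skeleton length counts pixels**, with no sqrt(2) correction for diagonal
  steps, mirroring pixel-counting on skeletonized images; this underestimates
  diagonal segments by up to ~8%. Zhang-Suen thinning also erodes each free
  line end by about half the vessel width; on a 5 x 41 px bar the centreline
  is 36 px. Noise creates small spurious foreground islands whose skeletons
  inflate VLD — recovery guarantees hold for noiseless phantoms.
* **Thinning** preserves 8-connected components (a guard prevents a
  component from vanishing entirely, e.g. an isolated 2 x 2 block) and is
  idempotent.
* **Polygon semantics**: ROIs are geometric polygons with continuous
  (sub-pixel) vertices, 0-based coordinates, pixel centres at half-integers.
  Rasterization uses the even-odd rule on pixel centres; window clipping is
  Sutherland-Hodgman against the column band. The circularity formula is the
  isoperimetric quotient with the perimeter squared. A 4:1 ellipse has
  circularity 0.5365 (exact elliptic integral), which the polygon pipeline
  reproduces to three decimals.
* **Severity coding**: the six-level group code is treated as numeric, so
  the report is one adjusted slope per severity step. Healthy controls are
  included in trend fits by default (configurable via `groups = 2:6`).
  Diagnostic contrasts use diabetic eyes only by default: no-DR (group 2)
  vs DR (3-6), and early (2-4) vs advanced (5-6); including the healthy
  group among negatives is available but off by default.
* **Mixed-model fallback**: with no repeated eyes, or a singular random
  intercept (as happens when the patient-level variance estimate hits
  zero), the fit falls back to ordinary least squares with a warning; at
  zero patient effect both estimators coincide.
* **Uncertainty**: AUC variance by the DeLong structural-components
  estimator (computed via midranks, verified against the brute-force double
  loop); sensitivity/specificity intervals by the Wilson score method.
  Youden ties break toward higher sensitivity, then the lower cutoff; with
  fully separated classes the reported cutoff is the midpoint of the gap.
  Both eyes of a patient enter ROC analyses as independent units (the
  eye is the unit of analysis); this ignores within-patient correlation and
  is a documented limitation.
* **p-value floor** `<0.001` is applied only when formatting, never to the
  stored values.

## Problem sizes used in the checks

The bundled tests and drivers run at the study's native scales: 320 x 320 px
en-face phantoms, 120 x 216 px choroid windows, the 174-eye reference cohort
for sign-pattern and contrast-size checks, cohorts of 500 eyes x 100
replicates for slope-recovery coverage, and 2,000 scores per class for the
closed-form binormal AUC limit (`AUC = Phi(delta / sqrt 2)`).

## Known limitations

* Absolute vessel densities depend on the (unknowable) acquisition and
  binarization settings of any given device; the package validates
  *structure* — recovery of known truth, monotonicity, trend directions —
  not absolute clinical values.
* Automatic FAZ or choroid segmentation is out of scope: outlines are
  inputs, as in the manual protocol.
* The fovea position on a B-scan is an input column, not detected.
* ImageJ's binary `.roi` format is not read; use the ROI JSON or CSV
  formats.
* The cohort generator's independence assumptions (above) make it
  unsuitable for studying cross-metric multivariate structure.

## A worked example

```{r example, eval = FALSE}
ph <- generate_enface_phantom(enface_phantom_spec(
  vessel_fraction_target = 0.35, noise_sd = 0, seed = 77))
q <- quantify_enface(ph$image)
q
#> vessel density 35.00%, vessel length density 13.569 /mm

faz_metrics(ph$truth_faz_polygon, ph$image)
#> FAZ area 0.411 mm^2, perimeter 2.324 mm, circularity 0.957

coh <- generate_cohort(cohort_spec(seed = 20))
fit_adjusted_trend(filter_quality(coh), "cvi")
#> cvi: adjusted beta -0.842 +/- 0.151 per severity step, p <0.001 (lmm, n=172)
```
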