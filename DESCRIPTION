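Package: octaquant
Title: Quantification of OCT Angiography Vascular Parameters Across
    Diabetic Retinopathy Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies retinal and choroidal vascular parameters from
    en-face OCT angiography images and choroidal B-scans, and evaluates
    them across diabetic retinopathy severity stages. Implements foveal
    avascular zone morphometry (area, perimeter, circularity index) from
    traced polygon outlines, Niblack local-threshold binarization with
    vessel density and skeleton-based vessel length density, the
    choroidal vascularity index on a subfoveal window, and cohort-level
    statistics: covariate-adjusted severity trends with eyes nested in
    patients, ROC curves with DeLong confidence intervals, and Youden
    cutoffs. A synthetic-data module generates vascular phantoms and
    six-group cohorts with known ground truth so every stage is testable
    without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
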