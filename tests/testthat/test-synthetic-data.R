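test_that("phantom generation is bit-reproducible for a fixed seed", {
  s <- enface_phantom_spec(image_px = 96, seed = 5)
  expect_identical(generate_enface_phantom(s), generate_enface_phantom(s))
  cs <- choroid_phantom_spec(seed = 5)
  expect_identical(generate_choroid_phantom(cs), generate_choroid_phantom(cs))
  ks <- cohort_spec(seed = 5)
  expect_identical(generate_cohort(ks), generate_cohort(ks))
})

test_that("an avascular, noiseless phantom is an empty network on a constant
          background", {
  ph <- generate_enface_phantom(enface_phantom_spec(
    vessel_fraction_target = 0, noise_sd = 0, seed = 1))
  expect_false(any(ph$truth_vessel_mask))
  outside <- !rasterize_polygon(ph$truth_faz_polygon, dim(ph$image$pixels))
  expect_true(all(ph$image$pixels[outside] == 30))
  expect_equal(ph$truth_vessel_fraction, 0)
  expect_equal(ph$truth_skeleton_length_mm, 0)
})

test_that("an unperturbed avascular-zone contour is circular and the truth
          fields are self-consistent", {
  ph <- generate_enface_phantom(enface_phantom_spec(
    faz_harmonic_amps = numeric(0), noise_sd = 0, seed = 2))
  s <- ph$image$scale_px_per_mm[["x"]]
  fm <- faz_metrics(ph$truth_faz_polygon, ph$image)
  expect_gte(fm$circularity, 0.99)
  expect_lt(abs(fm$area_mm2 - pi * 0.36^2) / (pi * 0.36^2), 0.01)
  # truth fields recomputed from the rasters, never echoed from the spec
  expect_equal(ph$truth_vessel_fraction, mean(ph$truth_vessel_mask))
  expect_equal(vessel_density(ph$truth_vessel_mask),
               100 * ph$truth_vessel_fraction)
  v <- ph$truth_faz_polygon$vertices
  expect_true(all(v >= 0 & v <= 320))
})

test_that("unreachable vessel targets and invalid specs raise errors", {
  expect_error(enface_phantom_spec(vessel_fraction_target = 1), "\\[0, 1\\)")
  expect_error(enface_phantom_spec(faz_mean_radius = 1.6), "half the extent")
  expect_error(enface_phantom_spec(image_px = 16), ">= 32")
  # a huge avascular zone leaves too little room for an 80% network
  expect_error(generate_enface_phantom(enface_phantom_spec(
    image_px = 64, faz_mean_radius = 1.4, faz_harmonic_amps = numeric(0),
    vessel_fraction_target = 0.8, seed = 1)), "unreachable")
})

test_that("choroid phantoms hit the luminal fraction and reject extremes", {
  ch0 <- generate_choroid_phantom(choroid_phantom_spec(
    true_luminal_fraction = 0, seed = 1))
  expect_false(any(ch0$truth_luminal_mask))
  ch <- generate_choroid_phantom(choroid_phantom_spec(
    true_luminal_fraction = 0.69, noise_sd = 0, seed = 3))
  expect_gte(ch$truth_luminal_fraction, 0.67)
  expect_lte(ch$truth_luminal_fraction, 0.71)
  tca <- rasterize_polygon(ch$tca_polygon, dim(ch$image$pixels))
  expect_equal(sum(ch$truth_luminal_mask) / sum(tca),
               ch$truth_luminal_fraction)
  expect_error(generate_choroid_phantom(choroid_phantom_spec(
    true_luminal_fraction = 0.96, seed = 1)), "too high")
})

test_that("cohorts have the published layout: 174 eyes across six groups", {
  coh <- generate_cohort(cohort_spec(seed = 6))
  expect_identical(nrow(coh), 174L)
  expect_identical(as.integer(table(coh$group)), c(42L, 30L, 22L, 23L, 42L, 15L))
  expect_false(anyDuplicated(coh$eye_id) > 0)
  # eyes of one patient stay within one group
  expect_true(all(tapply(coh$group, coh$patient_id,
                         function(g) length(unique(g))) == 1L))
  expect_true(all(table(coh$patient_id) <= 2))
})

test_that("degenerate cohorts collapse to the group means and impossible
          variance splits error", {
  zero_sd <- cohort_spec(
    group_metric_sds = dr_reference_params()$metric_sds * 0,
    patient_effect_sd = 0, seed = 1)
  coh <- generate_cohort(zero_sd)
  means <- dr_reference_params()$metric_means
  for (g in 1:6)
    expect_equal(unname(coh$cvi[coh$group == g]),
                 rep(means["cvi", g], sum(coh$group == g)))
  expect_error(cohort_spec(patient_effect_sd = 10), "residual variance")
})

test_that("large-cohort group means converge to the specified means", {
  coh <- generate_cohort(cohort_spec(group_sizes = rep(2000L, 6),
                                     patient_effect_sd = 0, seed = 31))
  ref <- dr_reference_params()
  for (m in c("cvi", "faz_circ_dcp", "vd_scp")) {
    for (g in 1:6) {
      se <- ref$metric_sds[m, g] / sqrt(2000)
      expect_lt(abs(mean(coh[[m]][coh$group == g]) - ref$metric_means[m, g]),
                3 * se)
    }
  }
})
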