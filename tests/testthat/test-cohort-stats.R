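test_that("quality filtering is strict at the threshold and idempotent", {
  coh <- generate_cohort(cohort_spec(seed = 3))
  coh$ssi <- 70
  expect_identical(nrow(filter_quality(coh)), nrow(coh))
  coh$ssi[1:5] <- 60          # exactly at the threshold: removed
  coh$ssi[6:10] <- 60.1
  f <- filter_quality(coh)
  expect_identical(nrow(f), nrow(coh) - 5L)
  expect_identical(attr(f, "n_removed"), 5L)
  expect_identical(nrow(f), sum(coh$ssi > 60))       # brute-force count
  f2 <- filter_quality(f)
  expect_identical(f2[names(coh)], f[names(coh)])    # idempotent
})

make_trend_cohort <- function(seed, slope, n_per_group = 84L,
                              sd = 3, pe = 1.5) {
  means <- matrix(69.21 + slope * (0:5), 1, 6, dimnames = list("cvi", NULL))
  sds <- matrix(sd, 1, 6, dimnames = list("cvi", NULL))
  generate_cohort(cohort_spec(group_sizes = rep(n_per_group, 6),
                              group_metric_means = means,
                              group_metric_sds = sds,
                              patient_effect_sd = pe, seed = seed))
}

test_that("the adjusted trend recovers a known severity slope", {
  coh <- make_trend_cohort(seed = 17, slope = -0.68)
  tr <- fit_adjusted_trend(coh, "cvi")
  expect_identical(tr$model, "lmm")
  expect_lt(abs(tr$beta - (-0.68)), 2 * tr$se)
  expect_lt(tr$p, 0.001)
})

test_that("without a patient effect the trend collapses to least squares", {
  coh <- make_trend_cohort(seed = 18, slope = -0.5, pe = 0)
  expect_warning(tr <- fit_adjusted_trend(coh, "cvi"), "OLS")
  ols <- lm(cvi ~ as.numeric(group) + age + sex + dbp, data = coh)
  expect_equal(tr$beta, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_identical(tr$model, "ols")
  # one eye per patient throughout: same fallback
  coh2 <- coh[!duplicated(coh$patient_id), ]
  expect_warning(tr2 <- fit_adjusted_trend(coh2, "cvi"), "one eye")
  expect_identical(tr2$model, "ols")
})

test_that("ROC curves are monotone, oriented, and match the rank-statistic
          oracle", {
  set.seed(41)
  for (i in 1:50) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    scores <- sample(1:8, n1 + n0, replace = TRUE)  # heavy ties
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    rc <- roc_points(scores, labels)
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[length(rc$tpr)], 1)
    auc_mw <- mw_auc(scores[labels], scores[!labels])
    expect_equal(rc$auc, max(auc_mw, 1 - auc_mw), tolerance = 1e-12)
    expect_gte(rc$auc, 0.5)
  }
  # perfect separation
  rc <- roc_points(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$auc, 1)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_error(roc_points(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(42)
  s <- rnorm(80); l <- rbinom(80, 1, 0.4)
  a1 <- roc_points(s, l)$auc
  expect_equal(roc_points(exp(s), l)$auc, a1)
  expect_equal(roc_points(s^3 + 2 * s, l)$auc, a1)
})

test_that("DeLong variance matches brute-force structural components", {
  set.seed(43)
  for (i in 1:50) {
    n1 <- sample(4:10, 1); n0 <- sample(4:10, 1)
    s <- sample(seq(0, 5, by = 0.5), n1 + n0, replace = TRUE)
    l <- c(rep(TRUE, n1), rep(FALSE, n0))
    if (length(unique(s[l])) == 1 && length(unique(s)) == 1) next
    a <- auc_with_ci(s, l)
    pos <- if (a$lower_indicates_disease) -s[l] else s[l]
    neg <- if (a$lower_indicates_disease) -s[!l] else s[!l]
    bf <- delong_naive(pos, neg)
    expect_equal(a$auc, bf$auc, tolerance = 1e-12)
    expect_equal(a$se^2, bf$var, tolerance = 1e-12)
  }
  a <- auc_with_ci(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(a$auc, 1); expect_equal(a$ci[2], 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  ours <- auc_with_ci(s, l)
  ref <- pROC::roc(l, s, quiet = TRUE, direction = "auto")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$ci,
               as.numeric(pROC::ci.auc(ref, method = "delong"))[c(1, 3)],
               tolerance = 1e-9)
})

test_that("Youden cutoffs match exhaustive search and the gap midpoint rule", {
  set.seed(45)
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    s <- sample(seq(0, 4, by = 0.25), n1 + n0, replace = TRUE)
    l <- c(rep(TRUE, n1), rep(FALSE, n0))
    y <- youden_cutoff(s, l)
    expect_equal(y$j, youden_naive(s, l), tolerance = 1e-12)
    expect_equal(y$j, y$sensitivity + y$specificity - 1, tolerance = 1e-12)
  }
  # separated classes: cutoff is the midpoint of the gap
  y <- youden_cutoff(c(0.1, 0.2, 0.3, 0.7, 0.8), c(1, 1, 1, 0, 0))
  expect_equal(y$j, 1)
  expect_equal(y$cutoff, 0.5)
  expect_true(y$lower_indicates_disease)
  # single overlap point: 2x2 table arithmetic
  y2 <- youden_cutoff(c(1, 2, 3, 3, 4, 5), c(1, 1, 1, 0, 0, 0))
  expect_equal(y2$sensitivity, 1)      # diseased <= 3 all called
  expect_equal(y2$specificity, 2 / 3)  # one healthy eye at 3 miscalled
})

test_that("diagnostic contrasts split the published group sizes correctly", {
  coh <- generate_cohort(cohort_spec(seed = 12))
  d1 <- diagnostic_table(coh, "faz_circ_dcp", "noDR_vs_DR")
  expect_identical(c(d1$n_neg, d1$n_pos), c(30L, 102L))
  d2 <- diagnostic_table(coh, "faz_circ_dcp", "early_vs_advanced")
  expect_identical(c(d2$n_neg, d2$n_pos), c(75L, 57L))
  expect_true(d1$lower_indicates_disease)
  # the deep-plexus circularity separates better than deep-plexus density
  dd <- diagnostic_table(coh, "vd_dcp", "noDR_vs_DR")
  expect_gt(d1$auc, dd$auc)
  # degenerate metric
  coh$flat <- 1
  expect_warning(df <- diagnostic_table(coh, "flat", "noDR_vs_DR"),
                 "constant")
  expect_equal(df$auc, 0.5)
})
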