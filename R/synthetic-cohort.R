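# Synthetic six-group cohorts: per-eye vascular metrics with a
# patient-level random intercept (some patients contribute both eyes),
# plus age / sex / diastolic-BP / signal-strength covariates.

#' Reference cohort parameters for the six DR severity groups
#'
#' Published group-level summaries used as generator defaults: eyes per group
#' (healthy, no DR, mild NPDR, moderate NPDR, severe NPDR, PDR), the mean and
#' SD of each vascular metric per group, and covariate summaries (age, female
#' fraction, diastolic blood pressure). The healthy-control diastolic BP is
#' not reported and defaults to a normotensive 75 +/- 9 mmHg.
#'
#' Metrics: FAZ area (mm^2), FAZ perimeter (mm), FAZ circularity index,
#' vessel density (%) and vessel length density (1/mm) at the superficial
#' (`_scp`) and deep (`_dcp`) plexuses, and the choroidal vascularity index
#' (`cvi`, %).
#'
#' @return A list with `group_sizes`, `metric_means`, `metric_sds`
#'   (metric x group matrices), `age_mean`, `age_sd`, `female_fraction`,
#'   `dbp_mean`, `dbp_sd`.
#' @export
dr_reference_params <- function() {
  groups <- c("healthy", "noDR", "mildNPDR", "modNPDR", "sevNPDR", "PDR")
  metrics <- c("faz_area_scp", "faz_perim_scp", "faz_circ_scp",
               "vd_scp", "vld_scp",
               "faz_area_dcp", "faz_perim_dcp", "faz_circ_dcp",
               "vd_dcp", "vld_dcp", "cvi")
  means <- rbind(
    faz_area_scp  = c(0.40, 0.42, 0.41, 0.42, 0.47, 0.50),
    faz_perim_scp = c(2.54, 2.89, 3.05, 3.13, 3.34, 3.42),
    faz_circ_scp  = c(0.77, 0.62, 0.55, 0.54, 0.54, 0.51),
    vd_scp        = c(35.95, 35.90, 35.73, 35.14, 35.27, 34.77),
    vld_scp       = c(15.75, 14.50, 13.32, 12.51, 13.37, 13.38),
    faz_area_dcp  = c(0.52, 0.55, 0.60, 0.63, 0.60, 0.64),
    faz_perim_dcp = c(2.87, 3.27, 3.80, 3.69, 3.80, 4.01),
    faz_circ_dcp  = c(0.79, 0.65, 0.52, 0.53, 0.53, 0.51),
    vd_dcp        = c(34.95, 35.03, 34.94, 34.72, 34.70, 34.32),
    vld_dcp       = c(18.78, 18.42, 16.89, 16.80, 16.48, 16.83),
    cvi           = c(69.21, 67.06, 66.60, 66.18, 66.15, 63.10))
  sds <- rbind(
    faz_area_scp  = c(0.13, 0.10, 0.10, 0.11, 0.10, 0.17),
    faz_perim_scp = c(0.42, 0.42, 0.40, 0.49, 0.48, 0.54),
    faz_circ_scp  = c(0.14, 0.08, 0.07, 0.06, 0.10, 0.09),
    vd_scp        = c(0.59, 0.81, 0.85, 0.79, 0.84, 0.70),
    vld_scp       = c(2.93, 3.49, 3.46, 3.25, 2.64, 2.86),
    faz_area_dcp  = c(0.14, 0.18, 0.22, 0.21, 0.15, 0.19),
    faz_perim_dcp = c(0.53, 0.69, 0.73, 0.73, 0.06, 0.65),
    faz_circ_dcp  = c(0.15, 0.10, 0.07, 0.09, 0.09, 0.08),
    vd_dcp        = c(0.72, 0.75, 0.61, 0.87, 0.98, 0.96),
    vld_dcp       = c(2.32, 2.59, 3.04, 2.56, 1.88, 2.53),
    cvi           = c(2.24, 3.98, 3.03, 3.04, 2.63, 3.45))
  colnames(means) <- colnames(sds) <- groups
  list(
    group_sizes = stats::setNames(c(42L, 30L, 22L, 23L, 42L, 15L), groups),
    metric_means = means[metrics, , drop = FALSE],
    metric_sds = sds[metrics, , drop = FALSE],
    age_mean = stats::setNames(c(51.7, 55.9, 60.0, 58.7, 57.6, 57.6), groups),
    age_sd = stats::setNames(c(14.0, 13.5, 13.6, 12.9, 10.4, 9.9), groups),
    female_fraction =
      stats::setNames(c(0.714, 0.567, 0.500, 0.478, 0.524, 0.467), groups),
    dbp_mean = stats::setNames(c(75.0, 76.2, 78.6, 74.5, 76.4, 76.1), groups),
    dbp_sd = stats::setNames(c(9.0, 9.4, 8.2, 8.3, 10.9, 9.2), groups)
  )
}

#' Specification of a synthetic cohort
#'
#' Each eye's metric value is group mean + patient random intercept +
#' residual, with the residual SD scaled so the total SD matches the group
#' SD; both eyes of a bilateral patient share the intercept (and the
#' patient-level covariates). Metrics are generated independently of each
#' other and of the covariates.
#'
#' @param group_sizes six non-negative integers (eyes per group).
#' @param group_metric_means,group_metric_sds metric x group matrices with
#'   matching dimnames (defaults: [dr_reference_params()]).
#' @param patient_effect_sd between-patient random-intercept SD; a scalar or
#'   one value per metric. Must not exceed any group SD of that metric
#'   (default: half the smallest group SD per metric).
#' @param fraction_bilateral fraction of patients contributing two eyes.
#' @param covariate_model list with per-group `age_mean`, `age_sd`,
#'   `female_fraction`, `dbp_mean`, `dbp_sd` (defaults from
#'   [dr_reference_params()]); `ssi_mean`, `ssi_sd` for the signal strength
#'   index (defaults 75 and 8).
#' @param seed integer RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = dr_reference_params()$group_sizes,
                        group_metric_means = dr_reference_params()$metric_means,
                        group_metric_sds = dr_reference_params()$metric_sds,
                        patient_effect_sd = NULL,
                        fraction_bilateral = 0.6,
                        covariate_model = NULL,
                        seed = 1L) {
  if (length(group_sizes) != 6L || any(group_sizes < 0))
    stop("`group_sizes` must be six non-negative eye counts")
  group_metric_means <- as.matrix(group_metric_means)
  group_metric_sds <- as.matrix(group_metric_sds)
  if (!identical(dim(group_metric_means), dim(group_metric_sds)) ||
      ncol(group_metric_means) != 6L)
    stop("metric means and SDs must be metric x 6-group matrices")
  if (any(group_metric_sds < 0)) stop("group SDs must be non-negative")
  if (is.null(rownames(group_metric_means)))
    stop("`group_metric_means` needs metric row names")
  nm <- nrow(group_metric_means)
  min_sd <- apply(group_metric_sds, 1L, min)
  if (is.null(patient_effect_sd)) patient_effect_sd <- 0.5 * min_sd
  if (length(patient_effect_sd) == 1L)
    patient_effect_sd <- rep(patient_effect_sd, nm)
  patient_effect_sd <- stats::setNames(as.numeric(patient_effect_sd),
                                       rownames(group_metric_means))
  if (any(patient_effect_sd < 0))
    stop("`patient_effect_sd` must be non-negative")
  if (any(patient_effect_sd > min_sd + 1e-12))
    stop("patient_effect_sd exceeds a group SD: residual variance would be negative")
  if (fraction_bilateral < 0 || fraction_bilateral > 1)
    stop("`fraction_bilateral` must be in [0, 1]")
  ref <- dr_reference_params()
  cm <- list(age_mean = ref$age_mean, age_sd = ref$age_sd,
             female_fraction = ref$female_fraction,
             dbp_mean = ref$dbp_mean, dbp_sd = ref$dbp_sd,
             ssi_mean = 75, ssi_sd = 8)
  if (!is.null(covariate_model)) cm[names(covariate_model)] <- covariate_model
  structure(
    list(group_sizes = as.integer(group_sizes),
         group_metric_means = group_metric_means,
         group_metric_sds = group_metric_sds,
         patient_effect_sd = patient_effect_sd,
         fraction_bilateral = fraction_bilateral,
         covariate_model = cm, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic six-group cohort
#'
#' @param spec a [cohort_spec()].
#' @return A data frame (one row per eye) with columns `eye_id`,
#'   `patient_id`, `group` (1-6), `age`, `sex` (1 = female), `dbp`, `ssi`,
#'   then one column per metric. Deterministic for a fixed seed.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' nrow(coh)  # 174 with the default group sizes
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    metrics <- rownames(spec$group_metric_means)
    cm <- spec$covariate_model
    rows <- vector("list", 6L)
    for (g in 1:6) {
      n_eyes <- spec$group_sizes[g]
      if (n_eyes == 0L) next
      # partition eyes into patients (some bilateral)
      eyes_per_patient <- integer(0)
      remaining <- n_eyes
      while (remaining > 0L) {
        two <- remaining >= 2L && stats::runif(1L) < spec$fraction_bilateral
        eyes_per_patient <- c(eyes_per_patient, if (two) 2L else 1L)
        remaining <- remaining - (if (two) 2L else 1L)
      }
      n_pat <- length(eyes_per_patient)
      pid <- sprintf("G%d_P%03d", g, seq_len(n_pat))
      pat_of_eye <- rep(seq_len(n_pat), eyes_per_patient)
      age <- stats::rnorm(n_pat, cm$age_mean[g], cm$age_sd[g])
      sex <- as.integer(stats::runif(n_pat) < cm$female_fraction[g])
      dbp <- stats::rnorm(n_pat, cm$dbp_mean[g], cm$dbp_sd[g])
      df <- data.frame(
        eye_id = sprintf("%s_E%d", pid[pat_of_eye],
                         unlist(lapply(eyes_per_patient, seq_len))),
        patient_id = pid[pat_of_eye],
        group = g,
        age = age[pat_of_eye],
        sex = sex[pat_of_eye],
        dbp = dbp[pat_of_eye],
        ssi = round(stats::rnorm(n_eyes, cm$ssi_mean, cm$ssi_sd), 1),
        stringsAsFactors = FALSE)
      for (m in metrics) {
        pe <- spec$patient_effect_sd[m]
        res_sd <- sqrt(pmax(spec$group_metric_sds[m, g]^2 - pe^2, 0))
        b_pat <- stats::rnorm(n_pat, 0, pe)
        df[[m]] <- spec$group_metric_means[m, g] + b_pat[pat_of_eye] +
          stats::rnorm(n_eyes, 0, res_sd)
      }
      rows[[g]] <- df
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(out) <- NULL
    out
  })
}
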