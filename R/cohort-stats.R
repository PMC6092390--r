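# Cohort-level analysis: quality filtering, covariate-adjusted severity
# trends with eyes nested in patients, ROC / AUC (DeLong) / Youden cutoffs.

#' Filter eyes by signal strength index
#'
#' Retains scans whose signal strength index is strictly greater than the
#' threshold (scans at exactly the threshold are removed). Idempotent.
#'
#' @param cohort data frame with an `ssi` column.
#' @param ssi_min quality threshold (default 60).
#' @return The filtered cohort, with an attribute `n_removed`.
#' @export
filter_quality <- function(cohort, ssi_min = 60) {
  if (!"ssi" %in% names(cohort)) stop("cohort has no `ssi` column")
  keep <- cohort$ssi > ssi_min
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Covariate-adjusted severity trend for one metric
#'
#' Fits `metric ~ severity + age + sex + dbp` with a patient-level random
#' intercept (eyes nested in patients), where severity is the ordinal group
#' code 1-6 treated as numeric. Reports the slope per severity step, its
#' standard error, and a two-tailed Wald p-value. When every patient
#' contributes a single eye, or the mixed fit is singular, the model
#' collapses to ordinary least squares (with a warning).
#'
#' @param cohort data frame with `group`, `patient_id`, `age`, `sex`, `dbp`
#'   and the metric column.
#' @param metric metric column name.
#' @param groups which severity groups to include (default all six; use
#'   `2:6` for the diabetic-eyes-only analysis).
#' @return A list of class `trend_result`: `metric`, `beta`, `se`, `p`,
#'   `model` ("lmm" or "ols"), `n`.
#' @export
fit_adjusted_trend <- function(cohort, metric, groups = 1:6) {
  if (!metric %in% names(cohort))
    stop(sprintf("metric '%s' not found in cohort", metric))
  d <- cohort[cohort$group %in% groups, , drop = FALSE]
  if (length(unique(d$group)) < 2L)
    stop("need at least two severity groups for a trend")
  d$severity <- as.numeric(d$group)
  d$y <- d[[metric]]
  fit_ols <- function() {
    fit <- stats::lm(y ~ severity + age + sex + dbp, data = d)
    cf <- summary(fit)$coefficients["severity", ]
    list(beta = cf[["Estimate"]], se = cf[["Std. Error"]], model = "ols")
  }
  res <- NULL
  if (max(table(d$patient_id)) > 1L) {
    fit <- tryCatch(
      suppressMessages(lme4::lmer(
        y ~ severity + age + sex + dbp + (1 | patient_id), data = d)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      cf <- summary(fit)$coefficients["severity", ]
      res <- list(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
                  model = "lmm")
    } else {
      warning("mixed model unavailable or singular; falling back to OLS",
              call. = FALSE)
    }
  } else {
    warning("one eye per patient throughout; falling back to OLS",
            call. = FALSE)
  }
  if (is.null(res)) res <- fit_ols()
  z <- res$beta / res$se
  structure(
    list(metric = metric, beta = res$beta, se = res$se,
         p = 2 * stats::pnorm(-abs(z)), model = res$model, n = nrow(d)),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("%s: adjusted beta %.3f +/- %.3f per severity step, p %s (%s, n=%d)\n",
              x$metric, x$beta, x$se, format_p(x$p), x$model, x$n))
  invisible(x)
}

#' Adjusted trends for several metrics
#'
#' @param cohort cohort data frame.
#' @param metrics metric column names (default: all metric columns).
#' @param groups severity groups to include.
#' @return Data frame with one row per metric: `metric`, `beta`, `se`, `p`,
#'   `model`, `n`.
#' @export
trend_table <- function(cohort, metrics = NULL, groups = 1:6) {
  if (is.null(metrics))
    metrics <- setdiff(names(cohort),
                       c("eye_id", "patient_id", "group", "age", "sex",
                         "dbp", "ssi"))
  rows <- lapply(metrics, function(m) {
    tr <- fit_adjusted_trend(cohort, m, groups)
    data.frame(metric = m, beta = tr$beta, se = tr$se, p = tr$p,
               model = tr$model, n = tr$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# p-value display floor, applied only at the formatting layer
format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

check_two_classes <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (!any(labels) || all(labels))
    stop("both classes must be non-empty")
  list(scores = scores, labels = labels)
}

#' ROC curve points
#'
#' Sweeps all distinct thresholds; the curve runs from (0, 0) to (1, 1) and
#' is monotone non-decreasing in both coordinates. Orientation is chosen
#' automatically so that the AUC is at least 0.5; when the negated score is
#' used (low metric values indicating disease, as for circularity or vessel
#' density), `lower_indicates_disease` is `TRUE`.
#'
#' @param scores numeric metric values.
#' @param labels binary disease labels (`TRUE`/1 = diseased).
#' @return A list of class `roc_curve`: `fpr`, `tpr`, `thresholds` (on the
#'   original score scale), `auc`, `lower_indicates_disease`.
#' @export
roc_points <- function(scores, labels) {
  cl <- check_two_classes(scores, labels)
  scores <- cl$scores; labels <- cl$labels
  build <- function(s) {
    th <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(s[labels] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(s[!labels] >= t), numeric(1))
    list(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
         thresholds = c(Inf, th, -Inf))
  }
  trap <- function(cv) sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) +
                                             utils::tail(cv$tpr, -1)) / 2)
  cv <- build(scores)
  auc <- trap(cv)
  flipped <- FALSE
  if (auc < 0.5) {
    cv <- build(-scores)
    cv$thresholds <- -cv$thresholds
    auc <- trap(cv)
    flipped <- TRUE
  }
  structure(
    list(fpr = cv$fpr, tpr = cv$tpr, thresholds = cv$thresholds,
         auc = auc, lower_indicates_disease = flipped),
    class = "roc_curve"
  )
}

# Fast DeLong AUC variance via midranks (positives X, negatives Y on an
# oriented scale where higher = diseased).
delong_variance <- function(x, y) {
  m <- length(x); n <- length(y)
  rz <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rz[seq_len(m)] - rx) / n
  v01 <- 1 - (rz[m + seq_len(n)] - ry) / m
  theta <- mean(v10)
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  list(auc = theta, var = s10 / m + s01 / n)
}

#' AUC with a DeLong 95% confidence interval
#'
#' Trapezoidal AUC (equal to the tie-corrected Mann-Whitney statistic) with
#' the DeLong structural-components variance estimator; the normal-theory CI
#' is clipped to `[0, 1]`. Orientation follows [roc_points()].
#'
#' @inheritParams roc_points
#' @param conf confidence level (default 0.95).
#' @return A list: `auc`, `ci` (length 2), `se`, `lower_indicates_disease`.
#' @export
auc_with_ci <- function(scores, labels, conf = 0.95) {
  cl <- check_two_classes(scores, labels)
  scores <- cl$scores; labels <- cl$labels
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least two members per class for a CI")
  rc <- roc_points(scores, labels)
  s <- if (rc$lower_indicates_disease) -scores else scores
  dl <- delong_variance(s[labels], s[!labels])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(dl$var)
  list(auc = rc$auc,
       ci = c(max(0, rc$auc - half), min(1, rc$auc + half)),
       se = sqrt(dl$var),
       lower_indicates_disease = rc$lower_indicates_disease)
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - half), min(1, ctr + half))
}

#' Youden-index cutoff with sensitivity and specificity
#'
#' Maximises J = sensitivity + specificity - 1 over candidate thresholds (the
#' midpoints between consecutive distinct score values, plus open ends). Ties
#' are broken toward the cutoff with higher sensitivity, then the lower
#' threshold. Sensitivity/specificity confidence intervals use the Wilson
#' score method. Orientation follows [roc_points()]: with
#' `lower_indicates_disease`, eyes at or below the cutoff are called
#' diseased; otherwise eyes at or above it.
#'
#' @inheritParams roc_points
#' @param conf confidence level for the Wilson intervals.
#' @return A list of class `youden_result`: `cutoff`, `j`, `sensitivity`,
#'   `specificity`, `sens_ci`, `spec_ci`, `lower_indicates_disease`.
#' @export
youden_cutoff <- function(scores, labels, conf = 0.95) {
  cl <- check_two_classes(scores, labels)
  scores <- cl$scores; labels <- cl$labels
  rc <- roc_points(scores, labels)
  s <- if (rc$lower_indicates_disease) -scores else scores
  sv <- sort(unique(s))
  cand <- c(sv[1L] - 1, (utils::head(sv, -1) + utils::tail(sv, -1)) / 2,
            sv[length(sv)] + 1)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  best <- NULL
  for (t in cand) {
    pred <- s >= t   # oriented scale: high = diseased
    sens <- sum(pred & labels) / n_pos
    spec <- sum(!pred & !labels) / n_neg
    j <- sens + spec - 1
    # oriented threshold t maps back to raw cutoff; "lower threshold" ties
    # are judged on the raw scale
    raw <- if (rc$lower_indicates_disease) -t else t
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
           (sens > best$sensitivity + 1e-12 ||
              (abs(sens - best$sensitivity) <= 1e-12 && raw < best$cutoff)))) {
      best <- list(cutoff = raw, j = j, sensitivity = sens,
                   specificity = spec)
    }
  }
  structure(
    c(best,
      list(sens_ci = wilson_ci(round(best$sensitivity * n_pos), n_pos, conf),
           spec_ci = wilson_ci(round(best$specificity * n_neg), n_neg, conf),
           lower_indicates_disease = rc$lower_indicates_disease)),
    class = "youden_result"
  )
}

#' Diagnostic evaluation of a metric for a DR-stage contrast
#'
#' Builds the binary contrast over diabetic eyes (groups 2-6; healthy
#' controls are excluded by default): `"noDR_vs_DR"` labels group 2 negative
#' and groups 3-6 positive; `"early_vs_advanced"` labels groups 2-4 negative
#' and groups 5-6 (severe NPDR, PDR) positive. Reports the DeLong AUC CI and
#' the Youden cutoff with Wilson CIs. A constant metric yields AUC 0.5 with a
#' warning.
#'
#' @param cohort cohort data frame.
#' @param metric metric column name.
#' @param contrast `"noDR_vs_DR"` or `"early_vs_advanced"`.
#' @param include_healthy include group 1 among the negatives (default
#'   `FALSE`).
#' @return A list of class `diagnostic_result`.
#' @export
diagnostic_table <- function(cohort, metric,
                             contrast = c("noDR_vs_DR", "early_vs_advanced"),
                             include_healthy = FALSE) {
  contrast <- match.arg(contrast)
  if (!metric %in% names(cohort))
    stop(sprintf("metric '%s' not found in cohort", metric))
  lo <- if (include_healthy) 1L else 2L
  d <- cohort[cohort$group >= lo & cohort$group <= 6L, , drop = FALSE]
  pos <- if (contrast == "noDR_vs_DR") d$group >= 3L else d$group >= 5L
  if (!any(pos) || all(pos))
    stop("a contrast class is empty after subsetting")
  scores <- d[[metric]]
  if (length(unique(scores)) == 1L) {
    warning("metric is constant; AUC set to 0.5", call. = FALSE)
    return(structure(
      list(metric = metric, contrast = contrast, auc = 0.5,
           auc_ci = c(0.5, 0.5), cutoff = NA_real_,
           sensitivity = NA_real_, specificity = NA_real_,
           sens_ci = c(NA_real_, NA_real_), spec_ci = c(NA_real_, NA_real_),
           lower_indicates_disease = NA,
           n_neg = sum(!pos), n_pos = sum(pos)),
      class = "diagnostic_result"))
  }
  a <- auc_with_ci(scores, pos)
  y <- youden_cutoff(scores, pos)
  structure(
    list(metric = metric, contrast = contrast,
         auc = a$auc, auc_ci = a$ci,
         cutoff = y$cutoff,
         sensitivity = y$sensitivity, specificity = y$specificity,
         sens_ci = y$sens_ci, spec_ci = y$spec_ci,
         lower_indicates_disease = a$lower_indicates_disease,
         n_neg = sum(!pos), n_pos = sum(pos)),
    class = "diagnostic_result"
  )
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: AUC %.3f (%.3f-%.3f), cutoff %.4g, sens %.1f%%, spec %.1f%%\n",
    x$metric, x$contrast, x$auc, x$auc_ci[1], x$auc_ci[2], x$cutoff,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Diagnostic tables for several metrics
#'
#' @inheritParams diagnostic_table
#' @param metrics metric column names.
#' @return Data frame, one row per metric, mirroring the columns of a
#'   diagnostic summary table (AUC and CI, cutoff, sensitivity and
#'   specificity with CIs).
#' @export
diagnostic_summary <- function(cohort, metrics,
                               contrast = c("noDR_vs_DR",
                                            "early_vs_advanced"),
                               include_healthy = FALSE) {
  contrast <- match.arg(contrast)
  rows <- lapply(metrics, function(m) {
    r <- diagnostic_table(cohort, m, contrast, include_healthy)
    data.frame(metric = m, contrast = contrast, auc = r$auc,
               auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
               cutoff = r$cutoff,
               sensitivity = r$sensitivity,
               sens_lo = r$sens_ci[1], sens_hi = r$sens_ci[2],
               specificity = r$specificity,
               spec_lo = r$spec_ci[1], spec_hi = r$spec_ci[2],
               lower_indicates_disease = r$lower_indicates_disease,
               n_neg = r$n_neg, n_pos = r$n_pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
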