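# Bland-Altman agreement analysis and robustness checks for paired
# cardiac-index measurements (test device vs reference method).
#
# Conventions: differences are test - reference; precision is the sample sd
# (n-1 denominator) of differences; limits of agreement (LoA) are
# bias +/- z * precision with z = 1.96 by default.

.as_pairs_df <- function(pairs) {
  if (inherits(pairs, "study_dataset")) pairs <- pairs$observations
  if (!is.data.frame(pairs)) stop("expected a data frame or study_dataset")
  if (!all(c("ci_test", "ci_ref") %in% names(pairs))) {
    stop("pairs must carry ci_test and ci_ref columns")
  }
  pairs$difference <- pairs$ci_test - pairs$ci_ref
  pairs$mean_pair <- (pairs$ci_test + pairs$ci_ref) / 2
  pairs
}

#' Bland-Altman agreement analysis
#'
#' Computes bias (mean of test-minus-reference differences), precision
#' (their sample sd), limits of agreement `bias +/- z * sd`, the mean
#' percentage error, and 95% confidence intervals for bias, both limits and
#' the MPE.
#'
#' @param pairs A `study_dataset` or data frame with `ci_test` and `ci_ref`
#'   columns (units L/min/m^2 for cardiac index, L/min for raw output).
#' @param z Coverage factor for the limits of agreement (default 1.96).
#' @param conf Confidence level for the intervals (default 0.95).
#' @return An object of class `agreement_result`: list with `n`, `bias`,
#'   `precision`, `loa_lower`, `loa_upper`, `grand_mean`, `mpe`, `ci_bias`,
#'   `ci_loa_lower`, `ci_loa_upper`, `ci_mpe` (each CI a length-2 vector),
#'   and `z`.
#' @examples
#' d <- data.frame(ci_test = c(2.5, 2.7, 3.0), ci_ref = c(2.4, 2.8, 2.9))
#' bland_altman(d)
#' @export
bland_altman <- function(pairs, z = 1.96, conf = 0.95) {
  pairs <- .as_pairs_df(pairs)
  d <- pairs$difference
  n <- length(d)
  if (n < 2) stop("bland_altman: need at least 2 pairs")
  bias <- mean(d)
  precision <- stats::sd(d)
  grand_mean <- mean(pairs$mean_pair)
  cis <- loa_confidence_intervals(bias, precision, n, z = z, conf = conf)
  structure(list(
    n = n,
    bias = bias,
    precision = precision,
    loa_lower = bias - z * precision,
    loa_upper = bias + z * precision,
    grand_mean = grand_mean,
    mpe = mpe(precision, grand_mean, z = z),
    ci_bias = cis$ci_bias,
    ci_loa_lower = cis$ci_loa_lower,
    ci_loa_upper = cis$ci_loa_upper,
    ci_mpe = mpe_ci(precision, grand_mean, n, z = z, conf = conf),
    z = z
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("Bland-Altman agreement analysis\n")
  cat(sprintf("  n pairs:    %d\n", x$n))
  cat(sprintf("  bias:       %.2f (95%% CI %.2f to %.2f)\n",
              x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  precision:  %.2f\n", x$precision))
  cat(sprintf("  LoA upper:  %.2f (95%% CI %.2f to %.2f)\n",
              x$loa_upper, x$ci_loa_upper[1], x$ci_loa_upper[2]))
  cat(sprintf("  LoA lower:  %.2f (95%% CI %.2f to %.2f)\n",
              x$loa_lower, x$ci_loa_lower[1], x$ci_loa_lower[2]))
  cat(sprintf("  MPE:        %.1f%% (95%% CI %.1f to %.1f)\n",
              x$mpe, x$ci_mpe[1], x$ci_mpe[2]))
  invisible(x)
}

#' Mean percentage error (Critchley criterion)
#'
#' `z * sd(differences) / mean cardiac index * 100`, the half-width of the
#' limits of agreement expressed as a percentage of the mean measurement.
#'
#' @param precision Sample sd of the differences (>= 0).
#' @param grand_mean Mean of the pair means (> 0).
#' @param z Coverage factor (default 1.96).
#' @return MPE, percent.
#' @export
mpe <- function(precision, grand_mean, z = 1.96) {
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("mpe: grand mean must be positive")
  }
  if (!is.finite(precision) || precision < 0) {
    stop("mpe: precision must be non-negative")
  }
  z * precision / grand_mean * 100
}

#' Confidence interval for the mean percentage error
#'
#' Propagates the chi-square sampling distribution of the sample sd
#' (df = n - 1) through the MPE formula, holding the grand mean fixed. This
#' is an approximation: it ignores sampling variability of the mean and any
#' repeated-measures correlation.
#'
#' @inheritParams mpe
#' @param n Number of pairs (>= 2).
#' @param conf Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper), percent.
#' @export
mpe_ci <- function(precision, grand_mean, n, z = 1.96, conf = 0.95) {
  if (n < 2) stop("mpe_ci: need n >= 2")
  a <- (1 - conf) / 2
  df <- n - 1
  sd_lo <- precision * sqrt(df / stats::qchisq(1 - a, df))
  sd_hi <- precision * sqrt(df / stats::qchisq(a, df))
  c(mpe(sd_lo, grand_mean, z), mpe(sd_hi, grand_mean, z))
}

#' Interchangeability verdict from the mean percentage error
#'
#' Clinical acceptability rule: MPE strictly below the threshold
#' (conventionally 30%).
#'
#' @param mpe_value MPE, percent (>= 0).
#' @param threshold Acceptability threshold, percent (default 30).
#' @return `TRUE` iff `mpe_value < threshold`.
#' @export
interchangeability <- function(mpe_value, threshold = 30) {
  if (mpe_value < 0 || threshold < 0) {
    stop("interchangeability: arguments must be non-negative")
  }
  mpe_value < threshold
}

#' Confidence intervals for bias and limits of agreement
#'
#' Bias CI: `bias +/- t(n-1, 1-a/2) * sd / sqrt(n)`. Each LoA CI uses the
#' standard-error form `sd * sqrt(1/n + z^2 / (2 (n-1)))` with the same t
#' multiplier.
#'
#' @param bias Mean difference.
#' @param precision Sample sd of differences (>= 0).
#' @param n Number of pairs (>= 2).
#' @param z Coverage factor of the LoA (default 1.96).
#' @param conf Confidence level (default 0.95).
#' @return List of length-2 vectors `ci_bias`, `ci_loa_lower`, `ci_loa_upper`.
#' @export
loa_confidence_intervals <- function(bias, precision, n, z = 1.96, conf = 0.95) {
  if (n < 2) stop("loa_confidence_intervals: need n >= 2")
  if (precision < 0) stop("loa_confidence_intervals: precision must be >= 0")
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- precision / sqrt(n)
  se_loa <- precision * sqrt(1 / n + z^2 / (2 * (n - 1)))
  list(
    ci_bias = bias + c(-1, 1) * tq * se_bias,
    ci_loa_lower = (bias - z * precision) + c(-1, 1) * tq * se_loa,
    ci_loa_upper = (bias + z * precision) + c(-1, 1) * tq * se_loa
  )
}

#' Shapiro-Wilk normality check on the differences
#'
#' First robustness step: decide whether parametric limits of agreement are
#' defensible. The caller branches on `p < 0.05`; both parametric and
#' percentile limits are reported side by side downstream regardless.
#'
#' @param differences Numeric vector, 3 <= n <= 5000.
#' @return List with `W` (statistic) and `p` (p-value).
#' @export
normality_check <- function(differences) {
  n <- length(differences)
  if (n < 3 || n > 5000) {
    stop("normality_check: Shapiro-Wilk supports 3 <= n <= 5000")
  }
  sw <- stats::shapiro.test(differences)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Non-parametric (percentile) limits of agreement
#'
#' Empirical 5th and 95th percentiles of the differences (default tails),
#' using the linear-interpolation quantile definition at position
#' `1 + (n-1) p` (R type 7). Alternative definitions can be selected via
#' `type` for sensitivity analysis.
#'
#' @param differences Numeric vector, n >= 2 (n >= 20 recommended).
#' @param tail_proportion Proportion excluded per tail (default 0.05).
#' @param type Quantile algorithm, passed to [stats::quantile()] (default 7).
#' @return Length-2 vector (lower, upper).
#' @export
nonparametric_loa <- function(differences, tail_proportion = 0.05, type = 7) {
  if (length(differences) < 2) stop("nonparametric_loa: need n >= 2")
  if (tail_proportion < 0 || tail_proportion >= 0.5) {
    stop("nonparametric_loa: tail_proportion must be in [0, 0.5)")
  }
  unname(stats::quantile(differences,
                         probs = c(tail_proportion, 1 - tail_proportion),
                         type = type, names = FALSE))
}

#' Repeated-measures-corrected limits of agreement
#'
#' Correction for multiple observations per patient when the true value
#' varies between timepoints: the total variance of the differences is
#' decomposed by patient with a one-way method-of-moments ANOVA,
#' `sd_total = sqrt(sigma2_between + sigma2_within)`, and the LoA are
#' `bias +/- z * sd_total`. With one observation per patient the correction
#' vanishes and the result equals the naive Bland-Altman LoA.
#'
#' @param differences Numeric vector of paired differences.
#' @param patient Grouping vector (patient id), same length.
#' @param z Coverage factor (default 1.96).
#' @return List with `loa_lower`, `loa_upper`, `sd_total`, `bias`,
#'   `sigma2_between`, `sigma2_within`.
#' @export
repeated_measures_loa <- function(differences, patient, z = 1.96) {
  if (length(differences) != length(patient)) {
    stop("repeated_measures_loa: differences and patient must align")
  }
  patient <- as.character(patient)
  k <- length(unique(patient))
  if (k < 2) {
    stop("repeated_measures_loa: need >= 2 patients to estimate the between-patient component")
  }
  N <- length(differences)
  bias <- mean(differences)
  ni <- tapply(differences, patient, length)
  mi <- tapply(differences, patient, mean)
  # one-way ANOVA, method of moments (unbalanced-safe)
  ss_within <- sum((differences - mi[patient])^2)
  df_within <- N - k
  ms_within <- if (df_within > 0) ss_within / df_within else 0
  ms_between <- sum(ni * (mi - bias)^2) / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  sigma2_between <- max(0, (ms_between - ms_within) / n0)
  sigma2_within <- ms_within
  sd_total <- sqrt(sigma2_between + sigma2_within)
  list(
    loa_lower = bias - z * sd_total,
    loa_upper = bias + z * sd_total,
    sd_total = sd_total,
    bias = bias,
    sigma2_between = sigma2_between,
    sigma2_within = sigma2_within
  )
}

#' Within-subject repeatability of one method, percent
#'
#' `z * within-subject sd / grand mean * 100`, with the within-subject sd
#' taken from a one-way ANOVA of replicates within subject-condition
#' (root mean square error).
#'
#' @param values Replicate measurements.
#' @param subject Subject-condition grouping vector (e.g. patient-timepoint).
#' @param z Coverage factor (default 1.96).
#' @return List with `repeatability` (percent), `sw` (within-subject sd),
#'   `grand_mean`.
#' @export
method_repeatability <- function(values, subject, z = 1.96) {
  subject <- as.character(subject)
  ni <- tapply(values, subject, length)
  if (sum(ni >= 2) < 2) {
    stop("method_repeatability: need >= 2 subjects with >= 2 replicates")
  }
  mi <- tapply(values, subject, mean)
  ss_within <- sum((values - mi[subject])^2)
  df_within <- length(values) - length(ni)
  if (df_within <= 0) stop("method_repeatability: no within-subject replication")
  sw <- sqrt(ss_within / df_within)
  gm <- mean(values)
  if (gm <= 0) stop("method_repeatability: grand mean must be positive")
  list(repeatability = z * sw / gm * 100, sw = sw, grand_mean = gm)
}

#' Combined repeatability of reference and test methods
#'
#' Root-sum-of-squares of the two per-method repeatabilities: the maximal
#' variation in repeated experimental and reference measurements that could
#' explain the mean error. Interchangeability is supported when the observed
#' MPE does not exceed the combined repeatability.
#'
#' @param replicates_ref,replicates_test Data frames with columns `subject`
#'   (subject-condition id) and `value` (replicate measurements) for the
#'   reference and test method respectively.
#' @param z Coverage factor (default 1.96).
#' @return List with `combined` (percent), `repeatability_ref`,
#'   `repeatability_test`.
#' @export
combined_repeatability <- function(replicates_ref, replicates_test, z = 1.96) {
  rr <- method_repeatability(replicates_ref$value, replicates_ref$subject, z = z)
  rt <- method_repeatability(replicates_test$value, replicates_test$subject, z = z)
  list(
    combined = sqrt(rr$repeatability^2 + rt$repeatability^2),
    repeatability_ref = rr$repeatability,
    repeatability_test = rt$repeatability
  )
}

#' Proportional-bias check via a random-intercept mixed model
#'
#' Fits `difference ~ ci_ref + (1 | patient)` by REML and tests the slope
#' against zero with a normal approximation on `slope / se` (adequate at the
#' sample sizes of a multi-timepoint validation study). A non-significant
#' slope supports a uniform bias over the measurement range.
#'
#' @param pairs A `study_dataset` or data frame with `patient_id`, `ci_ref`
#'   and either `difference` or both `ci_test`/`ci_ref`.
#' @return List with `slope`, `se`, `p`, and `uniform_bias`
#'   (`TRUE` when `p >= 0.05`).
#' @export
proportional_bias <- function(pairs) {
  pairs <- .as_pairs_df(pairs)
  if (length(unique(pairs$patient_id)) < 3) {
    stop("proportional_bias: need >= 3 patients")
  }
  if (length(unique(pairs$ci_ref)) < 2) {
    stop("proportional_bias: degenerate design, constant reference values")
  }
  fit <- lme4::lmer(difference ~ ci_ref + (1 | patient_id), data = pairs,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  slope <- unname(co["ci_ref"])
  slope_se <- unname(se[which(names(co) == "ci_ref")])
  p <- 2 * stats::pnorm(-abs(slope / slope_se))
  list(slope = slope, se = slope_se, p = p, uniform_bias = p >= 0.05)
}

#' Run the full battery of agreement robustness checks
#'
#' Convenience wrapper executing, on one paired dataset: the Shapiro-Wilk
#' normality check, the non-parametric percentile limits, the
#' repeated-measures-corrected limits, the proportional-bias mixed model and,
#' when replicate tables are supplied, combined repeatability.
#'
#' @param pairs A `study_dataset` or pairs data frame (needs `patient_id`).
#' @param replicates_ref,replicates_test Optional replicate tables for
#'   [combined_repeatability()].
#' @param z Coverage factor (default 1.96).
#' @return List of class `robustness_checks` with `shapiro_w`, `shapiro_p`,
#'   `np_loa_lower`, `np_loa_upper`, `corrected_loa_lower`,
#'   `corrected_loa_upper`, `sd_total`, `prop_slope`, `prop_slope_se`,
#'   `prop_slope_p`, `uniform_bias`, and `combined_repeatability` (NA when no
#'   replicate data).
#' @export
robustness_checks <- function(pairs, replicates_ref = NULL,
                              replicates_test = NULL, z = 1.96) {
  pairs <- .as_pairs_df(pairs)
  sw <- normality_check(pairs$difference)
  np <- nonparametric_loa(pairs$difference)
  rm <- repeated_measures_loa(pairs$difference, pairs$patient_id, z = z)
  pb <- proportional_bias(pairs)
  comb <- if (!is.null(replicates_ref) && !is.null(replicates_test)) {
    combined_repeatability(replicates_ref, replicates_test, z = z)$combined
  } else {
    NA_real_
  }
  structure(list(
    shapiro_w = sw$W, shapiro_p = sw$p,
    np_loa_lower = np[1], np_loa_upper = np[2],
    corrected_loa_lower = rm$loa_lower, corrected_loa_upper = rm$loa_upper,
    sd_total = rm$sd_total,
    prop_slope = pb$slope, prop_slope_se = pb$se, prop_slope_p = pb$p,
    uniform_bias = pb$uniform_bias,
    combined_repeatability = comb
  ), class = "robustness_checks")
}
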