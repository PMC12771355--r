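# Assembled validation report: agreement + robustness + trending + verdicts,
# JSON and plain-text renderings, and functional plots.

#' Interchangeability and trending verdicts
#'
#' Pure functions of the summary statistics: `mpe_acceptable` iff
#' MPE < threshold (default 30%); `trending_reliable` iff concordance > 90%,
#' |mean polar angle| < 5 degrees, angular sd <= 15 degrees and both radial
#' limits of agreement within +/- 30 degrees.
#'
#' @param mpe_value MPE, percent.
#' @param concordance Concordance rate, percent.
#' @param mean_angle Mean polar angle, degrees.
#' @param angle_sd Angular sd, degrees.
#' @param radial_loa_lower,radial_loa_upper Radial limits, degrees.
#' @param mpe_threshold Acceptability threshold (default 30).
#' @return List with logicals `mpe_acceptable` and `trending_reliable`.
#' @export
validation_verdicts <- function(mpe_value, concordance, mean_angle, angle_sd,
                                radial_loa_lower, radial_loa_upper,
                                mpe_threshold = 30) {
  list(
    mpe_acceptable = interchangeability(mpe_value, mpe_threshold),
    trending_reliable = (concordance > 90) &&
      (abs(mean_angle) < 5) &&
      (angle_sd <= 15) &&
      (radial_loa_lower > -30) && (radial_loa_upper < 30)
  )
}

#' Run the complete validation pipeline
#'
#' Executes, on one paired dataset: Bland-Altman agreement with confidence
#' intervals, all robustness checks, change-pair extraction and both trending
#' analyses, then derives the clinical verdicts.
#'
#' @param pairs A `study_dataset`, a pairs data frame, or a path to a
#'   long-format `pairs.csv` (see [read_pairs()]).
#' @param z Coverage factor (default 1.96).
#' @param mpe_threshold MPE acceptability threshold, percent (default 30).
#' @param zone_fraction Trending exclusion-zone fraction (default 0.15).
#' @param polar_scale Polar zone scale-down factor (default 1.5).
#' @param policy Change-pair policy (default `"consecutive_only"`).
#' @param replicates_ref,replicates_test Optional replicate tables for
#'   combined repeatability (columns `subject`, `value`).
#' @return List of class `validation_report` with components `agreement`,
#'   `robustness`, `trending`, `verdicts`, `config`.
#' @export
run_validation <- function(pairs, z = 1.96, mpe_threshold = 30,
                           zone_fraction = 0.15, polar_scale = 1.5,
                           policy = "consecutive_only",
                           replicates_ref = NULL, replicates_test = NULL) {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  obs <- .as_pairs_df(pairs)
  agr <- bland_altman(obs, z = z)
  rob <- robustness_checks(obs, replicates_ref = replicates_ref,
                           replicates_test = replicates_test, z = z)
  trd <- trending_analysis(obs, zone_fraction = zone_fraction,
                           polar_scale = polar_scale, policy = policy, z = z)
  ver <- validation_verdicts(agr$mpe, trd$concordance_rate,
                             trd$mean_polar_angle, trd$polar_sd,
                             trd$radial_loa_lower, trd$radial_loa_upper,
                             mpe_threshold = mpe_threshold)
  structure(list(
    agreement = agr,
    robustness = rob,
    trending = trd,
    verdicts = ver,
    config = list(z = z, mpe_threshold = mpe_threshold,
                  zone_fraction = zone_fraction, polar_scale = polar_scale,
                  policy = policy,
                  package_version = as.character(utils::packageVersion("coagree")))
  ), class = "validation_report")
}

#' Flatten a validation report to a named list of scalars
#'
#' Canonical machine-readable form behind the JSON rendering; deterministic
#' for identical inputs (no timestamps).
#'
#' @param report A `validation_report`.
#' @return Named list of scalars.
#' @export
report_fields <- function(report) {
  a <- report$agreement; r <- report$robustness; t <- report$trending
  list(
    n = a$n,
    bias = a$bias, precision = a$precision,
    loa_lower = a$loa_lower, loa_upper = a$loa_upper,
    grand_mean = a$grand_mean, mpe = a$mpe,
    ci_bias_lower = a$ci_bias[1], ci_bias_upper = a$ci_bias[2],
    ci_loa_lower_lower = a$ci_loa_lower[1], ci_loa_lower_upper = a$ci_loa_lower[2],
    ci_loa_upper_lower = a$ci_loa_upper[1], ci_loa_upper_upper = a$ci_loa_upper[2],
    ci_mpe_lower = a$ci_mpe[1], ci_mpe_upper = a$ci_mpe[2],
    shapiro_w = r$shapiro_w, shapiro_p = r$shapiro_p,
    np_loa_lower = r$np_loa_lower, np_loa_upper = r$np_loa_upper,
    corrected_loa_lower = r$corrected_loa_lower,
    corrected_loa_upper = r$corrected_loa_upper,
    combined_repeatability = r$combined_repeatability,
    prop_slope = r$prop_slope, prop_slope_se = r$prop_slope_se,
    prop_slope_p = r$prop_slope_p, uniform_bias = r$uniform_bias,
    n_changes = t$n_total, n_changes_excluded = t$n_excluded,
    concordance_rate = t$concordance_rate,
    mean_polar_angle = t$mean_polar_angle, polar_sd = t$polar_sd,
    radial_loa_lower = t$radial_loa_lower, radial_loa_upper = t$radial_loa_upper,
    zone_quadrant = t$zone_quadrant, zone_polar = t$zone_polar,
    mpe_acceptable = report$verdicts$mpe_acceptable,
    trending_reliable = report$verdicts$trending_reliable
  )
}

#' Render a validation report
#'
#' `"json"` emits the flat machine-readable document (lossless round trip);
#' `"text"` emits a human-readable table with cardiac-index quantities at 2
#' decimals and percents/degrees at 1 decimal.
#'
#' @param report A `validation_report`.
#' @param format `"json"` or `"text"`.
#' @return A character scalar (JSON) or character vector of lines (text).
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  f <- report_fields(report)
  if (format == "json") {
    return(jsonlite::toJSON(f, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  f2 <- function(x) formatC(x, format = "f", digits = 2)
  f1 <- function(x) formatC(x, format = "f", digits = 1)
  c(
    "Method-comparison validation report",
    "===================================",
    sprintf("pairs analysed        %d", f$n),
    sprintf("bias                  %s (95%% CI %s to %s)",
            f2(f$bias), f2(f$ci_bias_lower), f2(f$ci_bias_upper)),
    sprintf("precision (sd)        %s", f2(f$precision)),
    sprintf("upper LoA             %s (95%% CI %s to %s)",
            f2(f$loa_upper), f2(f$ci_loa_upper_lower), f2(f$ci_loa_upper_upper)),
    sprintf("lower LoA             %s (95%% CI %s to %s)",
            f2(f$loa_lower), f2(f$ci_loa_lower_lower), f2(f$ci_loa_lower_upper)),
    sprintf("MPE                   %s%% (95%% CI %s to %s)",
            f1(f$mpe), f1(f$ci_mpe_lower), f1(f$ci_mpe_upper)),
    sprintf("non-parametric LoA    %s to %s", f2(f$np_loa_lower), f2(f$np_loa_upper)),
    sprintf("corrected LoA         %s to %s",
            f2(f$corrected_loa_lower), f2(f$corrected_loa_upper)),
    sprintf("combined repeatab.    %s", if (is.na(f$combined_repeatability))
      "n/a (no replicate data)" else paste0(f1(f$combined_repeatability), "%")),
    sprintf("proportional slope    %s (p = %s)", f2(f$prop_slope),
            format.pval(f$prop_slope_p, digits = 3)),
    sprintf("concordance rate      %s%%", f1(f$concordance_rate)),
    sprintf("mean polar angle      %s deg (sd %s)",
            f1(f$mean_polar_angle), f1(f$polar_sd)),
    sprintf("radial LoA            %s to %s deg",
            f1(f$radial_loa_lower), f1(f$radial_loa_upper)),
    sprintf("MPE acceptable        %s", f$mpe_acceptable),
    sprintf("trending reliable     %s", f$trending_reliable)
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference vs pair mean with the bias line, both limits of agreement, and
#' shaded 95% confidence bands for each.
#'
#' @param pairs A `study_dataset` or pairs data frame.
#' @param result Optional precomputed [bland_altman()] result.
#' @param ... Passed to [graphics::plot()].
#' @return The `agreement_result`, invisibly.
#' @export
plot_bland_altman <- function(pairs, result = NULL, ...) {
  obs <- .as_pairs_df(pairs)
  if (is.null(result)) result <- bland_altman(obs)
  xr <- range(obs$mean_pair)
  plot(obs$mean_pair, obs$difference,
       xlab = "Mean of pair (L/min/m²)",
       ylab = "Difference test - reference (L/min/m²)",
       pch = 19, col = grDevices::adjustcolor("black", 0.6),
       ylim = range(c(obs$difference, result$ci_loa_lower, result$ci_loa_upper)),
       ...)
  band <- function(ci, col) {
    graphics::rect(xr[1], ci[1], xr[2], ci[2],
                   col = grDevices::adjustcolor(col, 0.2), border = NA)
  }
  band(result$ci_bias, "purple")
  band(result$ci_loa_lower, "purple")
  band(result$ci_loa_upper, "purple")
  graphics::abline(h = result$bias, lwd = 2)
  graphics::abline(h = c(result$loa_lower, result$loa_upper), lty = 2)
  invisible(result)
}

#' Four-quadrant trending plot
#'
#' Reference vs test change pairs with the identity line and the central
#' square exclusion zone.
#'
#' @param changes Output of [change_pairs()].
#' @param zone Exclusion-zone half-width.
#' @param ... Passed to [graphics::plot()].
#' @return `NULL`, invisibly.
#' @export
plot_four_quadrant <- function(changes, zone, ...) {
  lim <- range(c(changes$delta_ref, changes$delta_test, -zone, zone))
  plot(changes$delta_ref, changes$delta_test, asp = 1,
       xlab = "Δ reference (L/min/m²)",
       ylab = "Δ test (L/min/m²)",
       xlim = lim, ylim = lim, pch = 19,
       col = grDevices::adjustcolor("black", 0.6), ...)
  graphics::rect(-zone, -zone, zone, zone,
                 col = grDevices::adjustcolor("purple", 0.2), border = NA)
  graphics::abline(h = 0, v = 0, col = "grey50")
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}

#' Polar trending plot (half-circle convention)
#'
#' Change pairs as angle from the identity line vs mean-change magnitude,
#' with the central exclusion disc, the mean polar angle and the radial
#' limits of agreement drawn as rays.
#'
#' @param points Output of [polar_transform()].
#' @param zone_polar Polar exclusion radius.
#' @param stats Optional precomputed [polar_stats()] result.
#' @param ... Passed to [graphics::plot()].
#' @return The polar statistics, invisibly.
#' @export
plot_polar_trend <- function(points, zone_polar = 0, stats = NULL, ...) {
  if (is.null(stats)) stats <- polar_stats(points, zone_polar = zone_polar)
  r <- points$radius
  th <- points$angle * pi / 180
  rmax <- max(r) * 1.05
  plot(r * cos(th), r * sin(th), asp = 1,
       xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
       xlab = "Mean ΔCI along identity (L/min/m²)",
       ylab = "", pch = 19, col = grDevices::adjustcolor("black", 0.6), ...)
  tt <- seq(0, 2 * pi, length.out = 200)
  graphics::polygon(zone_polar * cos(tt), zone_polar * sin(tt),
                    col = grDevices::adjustcolor("purple", 0.2), border = NA)
  ray <- function(a_deg, ...) {
    a <- a_deg * pi / 180
    graphics::segments(0, 0, rmax * cos(a), rmax * sin(a), ...)
  }
  ray(stats$mean_polar_angle, lwd = 2, lty = 2)
  ray(stats$radial_loa_lower, lty = 3)
  ray(stats$radial_loa_upper, lty = 3)
  invisible(stats)
}
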