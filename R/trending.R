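# Trending-ability analysis: between-timepoint change pairs, four-quadrant
# concordance with a central exclusion zone, and polar-plot statistics.

#' Between-timepoint change pairs
#'
#' Per patient, the change in cardiac index between protocol timepoints, for
#' the reference and the test method. The default policy uses consecutive
#' timepoints only (the five ordered perioperative states make consecutive
#' transitions the physiologically meaningful ones); `"bridge"` additionally
#' spans a single missing timepoint.
#'
#' @param dataset A `study_dataset` or pairs data frame with `patient_id`,
#'   `timepoint`, `ci_test`, `ci_ref`.
#' @param policy `"consecutive_only"` (default) or `"bridge"`.
#' @return Data frame with `patient_id`, `from_timepoint`, `to_timepoint`,
#'   `delta_ref`, `delta_test`. May have zero rows.
#' @export
change_pairs <- function(dataset, policy = c("consecutive_only", "bridge")) {
  policy <- match.arg(policy)
  obs <- .as_pairs_df(dataset)
  out <- list()
  for (pid in unique(obs$patient_id)) {
    p <- obs[obs$patient_id == pid, , drop = FALSE]
    p <- p[order(p$timepoint), , drop = FALSE]
    tps <- p$timepoint
    from <- integer(0); to <- integer(0)
    # consecutive transitions t -> t+1 with both endpoints observed
    cc <- tps[(tps + 1) %in% tps]
    from <- c(from, cc); to <- c(to, cc + 1)
    if (policy == "bridge") {
      # span a single gap: t -> t+2 when t+1 is missing
      bb <- tps[!((tps + 1) %in% tps) & (tps + 2) %in% tps]
      from <- c(from, bb); to <- c(to, bb + 2)
    }
    if (length(from) == 0) next
    i_from <- match(from, tps); i_to <- match(to, tps)
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid,
      from_timepoint = from,
      to_timepoint = to,
      delta_ref = p$ci_ref[i_to] - p$ci_ref[i_from],
      delta_test = p$ci_test[i_to] - p$ci_test[i_from],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(0), from_timepoint = integer(0),
                      to_timepoint = integer(0), delta_ref = numeric(0),
                      delta_test = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$from_timepoint, res$to_timepoint), ]
  rownames(res) <- NULL
  res
}

#' Exclusion-zone half-width for trending analysis
#'
#' Small changes are direction-noise-dominated and are excluded from
#' concordance statistics. The zone is a fixed fraction (default 15%) of the
#' mean cardiac index.
#'
#' @param mean_ci Mean cardiac index, L/min/m^2 (> 0).
#' @param fraction Fraction of the mean (default 0.15, in `[0, 1)`).
#' @return Zone half-width, L/min/m^2.
#' @examples
#' exclusion_zone(2.65)  # 0.3975, i.e. 0.40 at 2 decimals
#' @export
exclusion_zone <- function(mean_ci, fraction = 0.15) {
  if (!is.finite(mean_ci) || mean_ci <= 0) {
    stop("exclusion_zone: mean cardiac index must be positive")
  }
  if (fraction < 0 || fraction >= 1) {
    stop("exclusion_zone: fraction must be in [0, 1)")
  }
  fraction * mean_ci
}

#' Four-quadrant concordance rate
#'
#' A change pair is excluded when both deltas lie strictly inside the central
#' square (`|delta_ref| < zone` and `|delta_test| < zone`). Among included
#' pairs, a pair is concordant when the deltas have the same strict sign
#' (`delta_ref * delta_test > 0`); a zero delta on either axis counts as
#' discordant (conservative tie handling).
#'
#' @param changes Data frame with `delta_ref`, `delta_test` (see
#'   [change_pairs()]).
#' @param zone Exclusion-zone half-width (>= 0).
#' @return List with `rate` (percent), `n_included`, `n_excluded`,
#'   `n_concordant`.
#' @export
concordance_rate <- function(changes, zone) {
  if (zone < 0) stop("concordance_rate: zone must be >= 0")
  dr <- changes$delta_ref; dt <- changes$delta_test
  excluded <- abs(dr) < zone & abs(dt) < zone
  inc <- !excluded
  if (!any(inc)) stop("concordance_rate: no change pairs outside the exclusion zone")
  conc <- dr[inc] * dt[inc] > 0
  list(
    rate = 100 * sum(conc) / sum(inc),
    n_included = sum(inc),
    n_excluded = sum(excluded),
    n_concordant = sum(conc)
  )
}

#' Polar-coordinate transform of a change pair
#'
#' Maps `(delta_ref, delta_test)` to an angle measured from the line of
#' identity (the planar angle of the vector minus 45 degrees, so perfect
#' tracking gives 0) and a radius equal to the magnitude of the mean change
#' `|delta_ref + delta_test| / 2`. Points whose mean change is negative are
#' rotated by 180 degrees into the positive half plane (half-circle
#' convention), so angular statistics live on one sheet. Angles are reported
#' in (-180, 180]; a test change smaller than the reference change gives a
#' negative angle.
#'
#' @param delta_ref,delta_test Change by reference / test method.
#'   Vectorised; a pair with both deltas zero is an error (undefined
#'   direction).
#' @return Data frame with `angle` (degrees) and `radius` (same units as the
#'   deltas).
#' @examples
#' polar_transform(1, 1)   # angle 0, radius 1
#' polar_transform(1, 0)   # angle -45, radius 0.5
#' @export
polar_transform <- function(delta_ref, delta_test) {
  if (any(delta_ref == 0 & delta_test == 0)) {
    stop("polar_transform: (0, 0) has undefined direction")
  }
  ang <- atan2(delta_test, delta_ref) * 180 / pi - 45
  mean_change <- (delta_ref + delta_test) / 2
  ang <- ifelse(mean_change < 0, ang + 180, ang)
  # normalise to (-180, 180]
  ang <- ((ang + 180) %% 360) - 180
  ang[ang == -180] <- 180
  data.frame(angle = ang, radius = abs(mean_change))
}

#' Angular statistics of a polar trending plot
#'
#' Excludes points with radius below the polar exclusion zone, then reports
#' the arithmetic mean of the remaining angles (angular bias), their sample
#' sd, and radial limits of agreement `mean +/- z * sd`. A radius-weighted
#' mean is available as an option.
#'
#' @param points Data frame with `angle` and `radius` (see
#'   [polar_transform()]).
#' @param zone_polar Polar exclusion-zone radius (default 0).
#' @param z Coverage factor for the radial limits (default 1.96).
#' @param weighted If `TRUE`, radius-weight the mean angle (off by default;
#'   the plain mean is the conventional summary).
#' @return List with `mean_polar_angle`, `polar_sd`, `radial_loa_lower`,
#'   `radial_loa_upper` (degrees), `n_included`, `n_excluded`.
#' @export
polar_stats <- function(points, zone_polar = 0, z = 1.96, weighted = FALSE) {
  keep <- points$radius >= zone_polar
  a <- points$angle[keep]
  if (length(a) < 2) {
    stop("polar_stats: need >= 2 points outside the polar exclusion zone")
  }
  m <- if (weighted) {
    stats::weighted.mean(a, points$radius[keep])
  } else {
    mean(a)
  }
  s <- stats::sd(a)
  list(
    mean_polar_angle = m,
    polar_sd = s,
    radial_loa_lower = m - z * s,
    radial_loa_upper = m + z * s,
    n_included = sum(keep),
    n_excluded = sum(!keep)
  )
}

#' Polar exclusion-zone radius from the four-quadrant zone
#'
#' The polar plot's central disc uses the four-quadrant zone scaled down
#' (default factor 1.5), because the polar radius is the mean of two deltas
#' rather than a single delta.
#'
#' @param zone_quadrant Four-quadrant zone half-width (>= 0).
#' @param scale_factor Positive divisor (default 1.5).
#' @return Polar zone radius.
#' @export
polar_zone <- function(zone_quadrant, scale_factor = 1.5) {
  if (zone_quadrant < 0) stop("polar_zone: zone must be >= 0")
  if (scale_factor <= 0) stop("polar_zone: scale factor must be positive")
  zone_quadrant / scale_factor
}

#' Full trending analysis of a paired dataset
#'
#' Extracts change pairs, derives the exclusion zone from the dataset's mean
#' cardiac index, and computes four-quadrant concordance plus polar
#' statistics.
#'
#' @param dataset A `study_dataset` or pairs data frame.
#' @param zone_fraction Exclusion-zone fraction of the mean (default 0.15).
#' @param polar_scale Scale-down factor for the polar zone (default 1.5).
#' @param policy Change-pair policy, see [change_pairs()].
#' @param z Coverage factor (default 1.96).
#' @return List of class `trending_result` with `n_total`, `n_excluded`,
#'   `n_concordant`, `concordance_rate`, `mean_polar_angle`, `polar_sd`,
#'   `radial_loa_lower`, `radial_loa_upper`, `zone_quadrant`, `zone_polar`.
#' @export
trending_analysis <- function(dataset, zone_fraction = 0.15, polar_scale = 1.5,
                              policy = "consecutive_only", z = 1.96) {
  obs <- .as_pairs_df(dataset)
  ch <- change_pairs(obs, policy = policy)
  if (nrow(ch) == 0) stop("trending_analysis: no change pairs available")
  zone_q <- exclusion_zone(mean(obs$mean_pair), fraction = zone_fraction)
  conc <- concordance_rate(ch, zone_q)
  zone_p <- polar_zone(zone_q, polar_scale)
  nz <- !(ch$delta_ref == 0 & ch$delta_test == 0)
  pts <- polar_transform(ch$delta_ref[nz], ch$delta_test[nz])
  ps <- polar_stats(pts, zone_polar = zone_p, z = z)
  structure(list(
    n_total = nrow(ch),
    n_excluded = conc$n_excluded,
    n_concordant = conc$n_concordant,
    concordance_rate = conc$rate,
    mean_polar_angle = ps$mean_polar_angle,
    polar_sd = ps$polar_sd,
    radial_loa_lower = ps$radial_loa_lower,
    radial_loa_upper = ps$radial_loa_upper,
    zone_quadrant = zone_q,
    zone_polar = zone_p
  ), class = "trending_result")
}

#' @export
print.trending_result <- function(x, ...) {
  cat("Trending analysis (four-quadrant + polar)\n")
  cat(sprintf("  change pairs:     %d (%d excluded by zone %.2f)\n",
              x$n_total, x$n_excluded, x$zone_quadrant))
  cat(sprintf("  concordance:      %.1f%%\n", x$concordance_rate))
  cat(sprintf("  mean polar angle: %.1f deg (sd %.1f)\n",
              x$mean_polar_angle, x$polar_sd))
  cat(sprintf("  radial LoA:       %.1f to %.1f deg\n",
              x$radial_loa_lower, x$radial_loa_upper))
  invisible(x)
}
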