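# Independent oracles and small data builders used across test files.
# These deliberately recompute quantities by a different route than the
# package code (sort-and-index quantiles, cross/dot arctangent, hand ANOVA).

# Linear-interpolation quantile at position 1 + (n-1) p, via explicit
# sort-and-index (independent of stats::quantile).
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Signed angle from the identity line via the cross/dot product of
# (delta_ref, delta_test) with (1, 1), then the same half-circle rotation.
oracle_polar_angle <- function(dr, dt) {
  raw <- atan2(dt - dr, dr + dt) * 180 / pi
  raw <- ifelse((dr + dt) / 2 < 0, raw + 180, raw)
  raw <- ((raw + 180) %% 360) - 180
  raw[raw == -180] <- 180
  raw
}

# Build a pairs data frame from explicit difference/mean specifications.
make_pairs <- function(differences, means = 2.5, patient = NULL) {
  n <- length(differences)
  means <- rep_len(means, n)
  data.frame(
    patient_id = if (is.null(patient)) sprintf("P%03d", seq_len(n)) else patient,
    timepoint = rep(1L, n),
    ci_test = means + differences / 2,
    ci_ref = means - differences / 2,
    stringsAsFactors = FALSE
  )
}

# Long-format CSV builder for read_pairs tests.
write_long_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

complete_long <- function(n_patients = 2, n_timepoints = 5) {
  g <- expand.grid(patient_id = sprintf("P%02d", seq_len(n_patients)),
                   timepoint = seq_len(n_timepoints),
                   method = c("test", "reference"),
                   stringsAsFactors = FALSE)
  g$co_l_min <- 4 + 0.1 * g$timepoint + 0.05 * (g$method == "test")
  g
}
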