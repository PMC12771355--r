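# Synthetic perioperative study generator with known ground truth.
#
# Generative model (all on the cardiac-index scale, L/min/m^2):
#   true CI_it = timepoint_mean[t] + b_i,        b_i ~ N(0, sigma_between)
#   reference  = true + N(0, sigma_ref)
#   test       = true + device_bias + prop_coefficient * true + N(0, sigma_test)
# Each patient-timepoint set is lost independently with prob missing_rate.
# CO is back-computed as CI x BSA from generated biometrics, so the long CSV
# round-trips through the indexing chain. Sub-streams (biometrics, patient
# shifts, noise, missingness, echo) draw under seeds derived from the master
# seed in a fixed documented order, so adding a feature never shifts an
# existing stream.

.sub_seed <- function(seed, k) {
  # distinct, reproducible 31-bit sub-seeds per component
  as.integer((as.double(seed) * 1103515245 + 12345 * k) %% 2147483647)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  # rejection sampling: exact respect of the stated ranges
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Parameters of a synthetic method-comparison study
#'
#' Validating constructor for the ground-truth parameterisation. Defaults
#' come from [default_study_params()].
#'
#' @param n_patients Number of patients (>= 1).
#' @param timepoint_means Reference cardiac-index mean at each of the 5
#'   perioperative timepoints, L/min/m^2.
#' @param sigma_between Between-patient sd of the random level shift.
#' @param sigma_ref,sigma_test Independent measurement-noise sds per method.
#' @param device_bias Constant additive bias of the test method.
#' @param prop_coefficient Proportional-bias slope (difference grows with the
#'   true cardiac index).
#' @param replicate_cv Within-replicate-set coefficient of variation of the
#'   echo VTI traces.
#' @param missing_rate Probability that a patient-timepoint set is lost.
#' @param seed Master seed (integer).
#' @return List of class `synthetic_params`.
#' @export
synthetic_params <- function(n_patients = 55,
                             timepoint_means = c(2.76, 2.38, 2.50, 2.54, 3.02),
                             sigma_between = 0.30,
                             sigma_ref = 0.14,
                             sigma_test = 0.14,
                             device_bias = 0.02,
                             prop_coefficient = 0,
                             replicate_cv = 0.15,
                             missing_rate = 2 / 275,
                             seed = 1L) {
  if (n_patients < 1) stop("synthetic_params: n_patients must be >= 1")
  if (length(timepoint_means) != 5 || any(timepoint_means <= 0)) {
    stop("synthetic_params: exactly 5 positive timepoint means required")
  }
  if (any(c(sigma_between, sigma_ref, sigma_test, replicate_cv) < 0)) {
    stop("synthetic_params: sds and CV must be >= 0")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("synthetic_params: missing_rate must be in [0, 1)")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    timepoint_means = timepoint_means,
    sigma_between = sigma_between,
    sigma_ref = sigma_ref,
    sigma_test = sigma_test,
    device_bias = device_bias,
    prop_coefficient = prop_coefficient,
    replicate_cv = replicate_cv,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_params")
}

#' Default synthetic-study parameters
#'
#' The stated world of the emulated validation study: 55 patients, the five
#' published reference timepoint means, a between-patient level-shift sd of
#' 0.30 (inducing the within-patient correlation that motivates the
#' repeated-measures correction), per-method noise sds of 0.14 (so the
#' theoretical MPE `1.96 * sqrt(2 * 0.14^2) / 2.65 * 100` is about 14.6%,
#' inside the published MPE confidence interval), a device bias of 0.02, no
#' proportional bias, a per-trace VTI coefficient of variation of 0.15
#' (consistent both with the published combined repeatability of about 40%
#' and, after averaging three sets of three traces, with the 0.14 reference
#' noise sd), and a missing rate of 2/275 (two sets lost out of 275).
#'
#' @param seed Master seed (default 1).
#' @return A `synthetic_params` object.
#' @export
default_study_params <- function(seed = 1L) {
  synthetic_params(seed = seed)
}

#' Generate cohort biometrics
#'
#' Truncated-normal biometrics matching the published cohort summaries
#' (women undergoing gynaecological laparoscopy): height ~ N(163.7, 6.3) on
#' [149, 176] cm, weight ~ N(66.5, 11.4) on [44, 93] kg, age ~ N(44.1, 10.8)
#' on [23, 77] yr; ASA class drawn from the published 8/45/2 proportions.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return Data frame: `patient_id`, `age_yr`, `height_cm`, `weight_kg`,
#'   `asa_class`, `sex`.
#' @export
generate_biometrics <- function(n, seed = 1L) {
  if (n < 1) stop("generate_biometrics: n must be >= 1")
  set.seed(.sub_seed(seed, 1L))
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_yr = .rtruncnorm(n, 44.1, 10.8, 23, 77),
    height_cm = .rtruncnorm(n, 163.7, 6.3, 149, 176),
    weight_kg = .rtruncnorm(n, 66.5, 11.4, 44, 93),
    asa_class = sample(1:3, n, replace = TRUE, prob = c(8, 45, 2) / 55),
    sex = "F",
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic study
#'
#' Draws biometrics, true per-patient-timepoint cardiac indices, paired
#' noisy readings for both methods, missingness, and (optionally) echo-level
#' raw measurements: a fixed aortic diameter per patient and three sets of
#' three VTI traces per measurement whose implied cardiac output matches the
#' reference reading in expectation (multiplicative trace noise with CV
#' `replicate_cv`).
#'
#' @param params A `synthetic_params` object.
#' @param echo If `TRUE`, also generate the echo-level raw table.
#' @return List with `dataset` (a `study_dataset`), `truth` (data frame of
#'   true cardiac indices with the missingness flags), `params`, and, when
#'   requested, `echo` (long replicate table: `patient_id`, `timepoint`,
#'   `aortic_diameter_cm`, `set_idx`, `trace_idx`, `vti_cm`,
#'   `heart_rate_bpm`).
#' @export
generate_study <- function(params = default_study_params(), echo = FALSE) {
  stopifnot(inherits(params, "synthetic_params"))
  n <- params$n_patients
  tp <- seq_along(params$timepoint_means)
  bio <- generate_biometrics(n, seed = params$seed)
  bsa <- mosteller_bsa(bio$height_cm, bio$weight_kg)

  set.seed(.sub_seed(params$seed, 2L))
  b_i <- stats::rnorm(n, 0, params$sigma_between)

  grid <- expand.grid(pt = seq_len(n), t = tp)
  true_ci <- params$timepoint_means[grid$t] + b_i[grid$pt]

  set.seed(.sub_seed(params$seed, 3L))
  ref <- true_ci + stats::rnorm(nrow(grid), 0, params$sigma_ref)
  tst <- true_ci + params$device_bias + params$prop_coefficient * true_ci +
    stats::rnorm(nrow(grid), 0, params$sigma_test)
  # cardiac indices are physical quantities; keep them positive
  eps <- 1e-6
  ref <- pmax(ref, eps); tst <- pmax(tst, eps)

  set.seed(.sub_seed(params$seed, 4L))
  lost <- stats::runif(nrow(grid)) < params$missing_rate

  truth <- data.frame(
    patient_id = bio$patient_id[grid$pt],
    timepoint = grid$t,
    true_ci = true_ci,
    ci_ref = ref,
    ci_test = tst,
    lost = lost,
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$patient_id, truth$timepoint), ]
  rownames(truth) <- NULL

  kept <- truth[!truth$lost, , drop = FALSE]
  obs <- data.frame(
    patient_id = kept$patient_id,
    timepoint = kept$timepoint,
    ci_test = kept$ci_test,
    ci_ref = kept$ci_ref,
    difference = kept$ci_test - kept$ci_ref,
    mean_pair = (kept$ci_test + kept$ci_ref) / 2,
    stringsAsFactors = FALSE
  )
  rownames(obs) <- NULL
  dataset <- structure(
    list(observations = obs, patients = bio,
         orphans = obs[0, c("patient_id", "timepoint"), drop = FALSE]),
    class = "study_dataset"
  )

  out <- list(dataset = dataset, truth = truth, params = params)

  if (echo) {
    set.seed(.sub_seed(params$seed, 5L))
    diam <- .rtruncnorm(n, 2.0, 0.15, 1.5, 2.5)
    hr <- .rtruncnorm(nrow(kept), 70, 10, 40, 120)
    i_pt <- match(kept$patient_id, bio$patient_id)
    co_target <- kept$ci_ref * bsa[i_pt]            # L/min
    sv_target <- co_target * 1000 / hr              # mL
    vti_base <- sv_target / aortic_cross_section(diam[i_pt])
    reps <- expand.grid(set_idx = 1:3, trace_idx = 1:3)
    echo_rows <- kept[rep(seq_len(nrow(kept)), each = 9L),
                      c("patient_id", "timepoint")]
    echo_rows$aortic_diameter_cm <- rep(diam[i_pt], each = 9L)
    echo_rows$set_idx <- rep(reps$set_idx, nrow(kept))
    echo_rows$trace_idx <- rep(reps$trace_idx, nrow(kept))
    noise <- stats::rnorm(nrow(echo_rows), 0, params$replicate_cv)
    echo_rows$vti_cm <- pmax(rep(vti_base, each = 9L) * (1 + noise), 1e-3)
    echo_rows$heart_rate_bpm <- rep(hr, each = 9L)
    rownames(echo_rows) <- NULL
    out$echo <- echo_rows
  }
  out
}

#' Write a synthetic study to the long-format pairs CSV
#'
#' Emits the exchange schema consumed by [read_pairs()]: per observation one
#' `test` and one `reference` row with CO back-computed as CI x BSA and the
#' patient biometrics embedded, so reading the file re-derives the same
#' cardiac indices through the Mosteller chain.
#'
#' @param study Output of [generate_study()].
#' @param path Output CSV path.
#' @param echo_path Optional path for the echo replicate table (requires
#'   `generate_study(..., echo = TRUE)`).
#' @return `path`, invisibly.
#' @export
write_synthetic_study <- function(study, path, echo_path = NULL) {
  obs <- study$dataset$observations
  bio <- study$dataset$patients
  i <- match(obs$patient_id, bio$patient_id)
  bsa <- mosteller_bsa(bio$height_cm[i], bio$weight_kg[i])
  long <- data.frame(
    patient_id = rep(obs$patient_id, 2L),
    timepoint = rep(obs$timepoint, 2L),
    method = rep(c("test", "reference"), each = nrow(obs)),
    co_l_min = c(obs$ci_test * bsa, obs$ci_ref * bsa),
    height_cm = rep(bio$height_cm[i], 2L),
    weight_kg = rep(bio$weight_kg[i], 2L),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$patient_id, long$timepoint, long$method), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(echo_path)) {
    if (is.null(study$echo)) stop("write_synthetic_study: no echo table in study")
    utils::write.csv(study$echo, echo_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
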