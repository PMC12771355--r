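# Bland-Altman agreement analysis and the robustness-check battery.

test_that("bland_altman recovers closed-form cases", {
  # degenerate: all pairs identical
  same <- make_pairs(rep(0, 5), means = 2.5)
  r0 <- bland_altman(same)
  expect_equal(r0$bias, 0)
  expect_equal(r0$precision, 0)
  expect_equal(c(r0$loa_lower, r0$loa_upper), c(0, 0))
  expect_equal(r0$mpe, 0)

  # three-point set with sd exactly 1
  r1 <- bland_altman(make_pairs(c(-1, 0, 1), means = 3))
  expect_equal(r1$bias, 0)
  expect_equal(r1$precision, 1)
  expect_equal(r1$loa_lower, -1.96)
  expect_equal(r1$loa_upper, 1.96)

  expect_error(bland_altman(make_pairs(0.1)), "at least 2")
})

test_that("bland_altman on the summary-grid pseudo-pairs reproduces the published bias", {
  r <- bland_altman(table2_pseudo_pairs())
  expect_equal(round(r$bias, 2), 0.02)
  expect_equal(round(r$grand_mean, 2), 2.65)
})

test_that("parametric LoA are symmetric about the bias; permutation and scale behaviour", {
  set.seed(301)
  for (i in 1:10) {
    d <- rnorm(40, mean = runif(1, -0.2, 0.2), sd = runif(1, 0.05, 0.5))
    p <- make_pairs(d, means = runif(40, 2, 3.5))
    r <- bland_altman(p)
    expect_equal(r$loa_upper - r$bias, r$bias - r$loa_lower)

    rp <- bland_altman(p[sample(nrow(p)), ])
    expect_equal(rp$bias, r$bias)
    expect_equal(rp$precision, r$precision)

    k <- 2.7
    ps <- p
    ps$ci_test <- ps$ci_test * k
    ps$ci_ref <- ps$ci_ref * k
    rs <- bland_altman(ps)
    expect_equal(rs$bias, k * r$bias)
    expect_equal(rs$precision, k * r$precision)
    expect_equal(rs$loa_upper, k * r$loa_upper)
    expect_equal(rs$mpe, r$mpe)
  }
})

test_that("mpe follows the Critchley formula and the threshold is strict", {
  expect_equal(mpe(0, 5), 0)
  expect_equal(mpe(1.0, 10.0), 19.6)
  expect_equal(round(mpe(0.20, 2.65), 2), 14.79)
  expect_error(mpe(0.2, 0), "positive")
  expect_true(interchangeability(14.7, 30))
  expect_false(interchangeability(30, 30))
  expect_false(interchangeability(45.2, 30))
})

test_that("confidence intervals reproduce the published bias CI and collapse correctly", {
  cis <- loa_confidence_intervals(0.0241, 0.20, 273)
  expect_equal(round(cis$ci_bias, 2), c(0.00, 0.05))

  cis0 <- loa_confidence_intervals(0.1, 0, 50)
  expect_equal(cis0$ci_bias, c(0.1, 0.1))
  expect_equal(cis0$ci_loa_upper, c(0.1, 0.1))

  # asymptotic: bias CI half-width -> 1.96 / sqrt(n)
  n <- 10000
  cisn <- loa_confidence_intervals(0, 1, n)
  expect_equal(diff(cisn$ci_bias) / 2, 1.96 / sqrt(n), tolerance = 1e-3)
  expect_error(loa_confidence_intervals(0, 1, 1), "n >= 2")
})

test_that("normality check flags heavy tails and passes normal samples", {
  set.seed(77)
  heavy <- 0.2 * rt(500, df = 2)
  expect_lt(normality_check(heavy)$p, 0.05)

  pass <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    normality_check(rnorm(500))$p > 0.05
  }, logical(1))
  expect_gt(mean(pass), 0.5)
  expect_error(normality_check(c(0, 1)), "3 <= n")
})

test_that("nonparametric LoA: hand cases, outlier robustness, oracle agreement", {
  expect_equal(nonparametric_loa(rep(0.3, 10)), c(0.3, 0.3))
  expect_equal(nonparametric_loa(1:20), c(1.95, 19.05))

  set.seed(402)
  d <- rnorm(200, 0, 0.2)
  d_out <- c(d, 5)
  par_shift <- abs(bland_altman(make_pairs(d_out))$loa_upper -
                     bland_altman(make_pairs(d))$loa_upper)
  np_shift <- abs(nonparametric_loa(d_out)[2] - nonparametric_loa(d)[2])
  expect_gt(par_shift, np_shift)

  # property: equals the sort-and-index oracle on all sizes up to 50
  set.seed(403)
  for (n in 2:50) {
    x <- rnorm(n)
    expect_equal(nonparametric_loa(x),
                 c(oracle_quantile(x, 0.05), oracle_quantile(x, 0.95)))
  }
})

test_that("repeated-measures LoA: reduction, hand ANOVA, widening under clustering", {
  # one observation per patient: identical to the naive analysis
  set.seed(55)
  d <- rnorm(30, 0.05, 0.2)
  rm1 <- repeated_measures_loa(d, patient = seq_along(d))
  expect_equal(rm1$sd_total, sd(d))
  expect_equal(rm1$loa_upper, mean(d) + 1.96 * sd(d))

  # hand-computed two-patient example: within var 0, between-means var 2
  rm2 <- repeated_measures_loa(c(0, 0, 2, 2), patient = c("P1", "P1", "P2", "P2"))
  expect_equal(rm2$sd_total, sqrt(2), tolerance = 1e-12)
  expect_gt(rm2$sd_total, sd(c(0, 0, 2, 2)))  # naive sd 1.155

  expect_error(repeated_measures_loa(c(1, 2), patient = c("P1", "P1")),
               ">= 2 patients")

  # with positive between-patient variance the corrected LoA are wider
  st <- generate_study(synthetic_params(n_patients = 80, sigma_between = 0.3,
                                        seed = 21))
  obs <- st$dataset$observations
  # induce patient-level difference clustering so the correction bites
  set.seed(22)
  shift <- rnorm(length(unique(obs$patient_id)), 0, 0.1)
  names(shift) <- unique(obs$patient_id)
  obs$ci_test <- obs$ci_test + shift[obs$patient_id]
  d <- obs$ci_test - obs$ci_ref
  rm3 <- repeated_measures_loa(d, obs$patient_id)
  naive <- bland_altman(obs)
  expect_gt(rm3$loa_upper, naive$loa_upper)
  expect_lt(rm3$loa_lower, naive$loa_lower)
})

test_that("combined repeatability: Pythagorean combination and degeneracy", {
  # two methods with identical replicate structure combine as sqrt(2) x each
  set.seed(88)
  reps <- data.frame(
    subject = rep(sprintf("S%02d", 1:20), each = 3),
    value = 2.5 + rep(rnorm(20, 0, 0.1), each = 3) + rnorm(60, 0, 0.08)
  )
  rr <- method_repeatability(reps$value, reps$subject)
  cc <- combined_repeatability(reps, reps)
  expect_equal(cc$combined, sqrt(2) * rr$repeatability)
  expect_equal(cc$repeatability_ref, cc$repeatability_test)

  # analytic check of the per-method definition against a direct ANOVA fit
  fit <- stats::aov(value ~ factor(subject), data = reps)
  sw_oracle <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  expect_equal(rr$sw, sw_oracle)
  expect_equal(rr$repeatability, 1.96 * sw_oracle / mean(reps$value) * 100)

  # zero within-replicate variance in one method: combined equals the other
  flat <- data.frame(subject = rep(c("S1", "S2"), each = 3), value = 2.5)
  cc2 <- combined_repeatability(flat, reps)
  expect_equal(cc2$combined, cc2$repeatability_test)

  # rep 10% and 10% combine to 14.14%
  expect_equal(round(sqrt(10^2 + 10^2), 2), 14.14)
  expect_error(method_repeatability(1:3, c("a", "b", "c")), "replicates")
})

test_that("proportional-bias model recovers a planted slope and stays null under independence", {
  # planted: difference = 0.1 * ci_ref + patient effect + small noise
  set.seed(501)
  n_pat <- 50
  tp_means <- c(2.76, 2.38, 2.50, 2.54, 3.02)
  pid <- rep(sprintf("P%03d", 1:n_pat), each = 5)
  ci_ref <- rep(tp_means, n_pat) + rnorm(n_pat * 5, 0, 0.25)
  u <- rnorm(n_pat, 0, 0.1)
  diff <- 0.1 * ci_ref + u[rep(1:n_pat, each = 5)] + rnorm(n_pat * 5, 0, 0.03)
  pairs <- data.frame(patient_id = pid, timepoint = rep(1:5, n_pat),
                      ci_ref = ci_ref, ci_test = ci_ref + diff)
  fit <- proportional_bias(pairs)
  expect_equal(fit$slope, 0.1, tolerance = 0.02 / 0.1)
  expect_lt(fit$p, 0.05)

  # null: differences independent of the reference values
  null_ok <- vapply(1:20, function(s) {
    set.seed(600 + s)
    ci_ref <- rep(tp_means, 30) + rnorm(150, 0, 0.25)
    diff <- rnorm(150, 0.02, 0.15)
    p <- data.frame(patient_id = rep(sprintf("P%03d", 1:30), each = 5),
                    ci_ref = ci_ref, ci_test = ci_ref + diff)
    proportional_bias(p)$p > 0.05
  }, logical(1))
  expect_gte(sum(null_ok), 15)

  degenerate <- data.frame(patient_id = rep(c("a", "b", "c"), 2),
                           ci_ref = 2.5, ci_test = 2.6)
  expect_error(proportional_bias(degenerate), "constant")
})

test_that("robustness_checks aggregates every field", {
  st <- generate_study(default_study_params(seed = 31), echo = TRUE)
  obs <- st$dataset$observations
  reps_ref <- data.frame(
    subject = paste(st$echo$patient_id, st$echo$timepoint),
    value = st$echo$vti_cm)
  rc <- robustness_checks(obs, replicates_ref = reps_ref,
                          replicates_test = reps_ref)
  expect_true(all(c("shapiro_w", "shapiro_p", "np_loa_lower", "np_loa_upper",
                    "corrected_loa_lower", "corrected_loa_upper",
                    "prop_slope", "prop_slope_se", "prop_slope_p",
                    "combined_repeatability") %in% names(rc)))
  expect_true(rc$np_loa_lower >= min(obs$difference))
  expect_true(rc$np_loa_upper <= max(obs$difference))
  expect_false(is.na(rc$combined_repeatability))
})
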