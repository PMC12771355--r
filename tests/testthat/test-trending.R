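# Four-quadrant concordance and polar-plot trending statistics.

test_that("change_pairs enumerates consecutive and bridged intervals", {
  obs <- data.frame(patient_id = "P01", timepoint = 1:5,
                    ci_ref = c(2.7, 2.4, 2.5, 2.6, 3.0),
                    ci_test = c(2.8, 2.4, 2.6, 2.5, 3.1))
  ch <- change_pairs(obs)
  expect_equal(nrow(ch), 4)
  expect_equal(ch$delta_ref, diff(obs$ci_ref))
  expect_equal(ch$delta_test, diff(obs$ci_test))

  gap <- obs[obs$timepoint != 4, ]
  cons <- change_pairs(gap, policy = "consecutive_only")
  expect_equal(cons$from_timepoint, c(1, 2))
  expect_equal(cons$to_timepoint, c(2, 3))
  bridged <- change_pairs(gap, policy = "bridge")
  expect_equal(nrow(bridged), 3)
  expect_true(any(bridged$from_timepoint == 3 & bridged$to_timepoint == 5))
})

test_that("change-pair count matches a brute-force enumeration on the fixture layout", {
  st <- generate_study(default_study_params(seed = 13))
  obs <- st$dataset$observations
  ch <- change_pairs(obs)
  # oracle: count (patient, t) with (patient, t+1) present, by explicit loop
  expected <- 0L
  for (pid in unique(obs$patient_id)) {
    tps <- obs$timepoint[obs$patient_id == pid]
    for (t in 1:4) expected <- expected + ((t %in% tps) && ((t + 1) %in% tps))
  }
  expect_equal(nrow(ch), expected)
})

test_that("exclusion_zone is a guarded product", {
  expect_equal(exclusion_zone(2.65, 0.15), 0.3975)
  expect_equal(round(exclusion_zone(2.65, 0.15), 2), 0.40)
  expect_equal(exclusion_zone(7, 0), 0)
  expect_equal(exclusion_zone(10, 0.15), 1.5)
  expect_error(exclusion_zone(-1), "positive")
  expect_error(exclusion_zone(2.65, 1), "fraction")
})

test_that("concordance_rate: identity, discordance, toy set, scale invariance", {
  ident <- data.frame(delta_ref = c(1, -1, 0.8), delta_test = c(1, -1, 0.8))
  expect_equal(concordance_rate(ident, 0.4)$rate, 100)

  flipped <- data.frame(delta_ref = c(1, -1), delta_test = c(-1, 1))
  expect_equal(concordance_rate(flipped, 0.4)$rate, 0)

  toy <- data.frame(delta_ref = c(1, 1, 0.1, -2), delta_test = c(1, -1, 0.1, -1.5))
  r <- concordance_rate(toy, 0.4)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$n_concordant, 2)
  expect_equal(r$n_included, 3)
  expect_equal(round(r$rate, 2), 66.67)

  for (k in c(0.5, 3, 10)) {
    rk <- concordance_rate(transform(toy, delta_ref = delta_ref * k,
                                     delta_test = delta_test * k), 0.4 * k)
    expect_equal(rk$rate, r$rate)
  }

  all_in <- data.frame(delta_ref = 0.01, delta_test = 0.01)
  expect_error(concordance_rate(all_in, 0.4), "outside")
})

test_that("polar_transform maps the identity line and axes correctly", {
  expect_equal(polar_transform(1, 1), data.frame(angle = 0, radius = 1))
  expect_equal(polar_transform(-1, -1), data.frame(angle = 0, radius = 1))
  p <- polar_transform(1, 0)
  expect_equal(p$angle, -45)
  expect_equal(p$radius, 0.5)
  expect_error(polar_transform(0, 0), "undefined")
})

test_that("polar_transform agrees with the cross/dot arctangent oracle", {
  set.seed(909)
  dr <- runif(10000, -2, 2)
  dt <- runif(10000, -2, 2)
  keep <- !(dr == 0 & dt == 0) & (dr + dt) != 0
  pts <- polar_transform(dr[keep], dt[keep])
  expect_equal(pts$angle, oracle_polar_angle(dr[keep], dt[keep]),
               tolerance = 1e-10)
  expect_equal(pts$radius, abs(dr[keep] + dt[keep]) / 2)
})

test_that("swapping the methods negates every angle and keeps radii", {
  set.seed(910)
  dr <- rnorm(500); dt <- rnorm(500)
  keep <- abs(dr + dt) > 1e-9 & abs(dr - dt) > 1e-9
  a <- polar_transform(dr[keep], dt[keep])
  b <- polar_transform(dt[keep], dr[keep])
  expect_equal(b$angle, -a$angle)
  expect_equal(b$radius, a$radius)
})

test_that("polar_stats: degenerate, two-point, exclusion, weighting", {
  ident <- polar_transform(c(1, 2, 0.5), c(1, 2, 0.5))
  s0 <- polar_stats(ident)
  expect_equal(s0$mean_polar_angle, 0)
  expect_equal(s0$polar_sd, 0)
  expect_equal(c(s0$radial_loa_lower, s0$radial_loa_upper), c(0, 0))

  two <- data.frame(angle = c(10, -10), radius = c(1, 1))
  s2 <- polar_stats(two)
  expect_equal(s2$mean_polar_angle, 0)
  expect_equal(round(s2$polar_sd, 2), 14.14)
  expect_equal(round(s2$radial_loa_upper, 2), 27.72)
  expect_equal(round(s2$radial_loa_lower, 2), -27.72)

  mixed <- data.frame(angle = c(0, 0, 50), radius = c(1, 1, 0.1))
  s3 <- polar_stats(mixed, zone_polar = 0.3)
  expect_equal(s3$n_excluded, 1)
  expect_equal(s3$mean_polar_angle, 0)

  w <- polar_stats(data.frame(angle = c(0, 30), radius = c(3, 1)),
                   weighted = TRUE)
  expect_equal(w$mean_polar_angle, 7.5)
  expect_error(polar_stats(data.frame(angle = 1, radius = 1)), ">= 2")
})

test_that("polar_zone scales the quadrant zone down", {
  expect_equal(round(polar_zone(0.40), 4), 0.2667)
  expect_equal(polar_zone(0), 0)
  expect_equal(polar_zone(0.3975, 1.5), 0.265)
  expect_error(polar_zone(0.4, 0), "positive")
  expect_error(polar_zone(-1), ">= 0")
})

test_that("concordance improves monotonically as tracking noise shrinks", {
  rates <- vapply(c(0.30, 0.15, 0.03), function(sig) {
    st <- generate_study(synthetic_params(n_patients = 80, sigma_ref = sig,
                                          sigma_test = sig, seed = 99))
    trending_analysis(st$dataset)$concordance_rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("trending_analysis assembles a coherent result", {
  st <- generate_study(default_study_params(seed = 5))
  tr <- trending_analysis(st$dataset)
  expect_s3_class(tr, "trending_result")
  expect_true(tr$concordance_rate >= 0 && tr$concordance_rate <= 100)
  expect_equal(tr$radial_loa_upper - tr$mean_polar_angle,
               tr$mean_polar_angle - tr$radial_loa_lower)
  expect_lte(tr$n_concordant, tr$n_total - tr$n_excluded)
  expect_equal(tr$zone_polar, tr$zone_quadrant / 1.5)
})
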