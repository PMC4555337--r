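test_that("covariate generator recovers the configured moments", {
  n <- 2e5
  cov <- draw_covariates(small_config(n = n))

  # corr(x1, x2) -> rho; SE of r is about (1 - rho^2) / sqrt(n)
  se_r <- (1 - 0.7^2) / sqrt(n)
  expect_lt(abs(cor(cov$x1, cov$x2) - 0.7), 4 * se_r)
  expect_lt(abs(var(cov$x1) - 1), 4 * sqrt(2 / n))
  expect_lt(abs(mean(cov$z) - 0.5), 4 * 0.5 / sqrt(n))

  # fraction of males with the one-week shift
  males <- cov$z == 1L
  frac <- mean(cov$shifted[males])
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / sum(males)))
  expect_true(all(cov$shifted[!males] == 0L))

  # E[x_ga] = 43 - E[chi2(3)] - P(male) * P(shift) = 39.975 weeks
  se_ga <- sqrt(2 * 3 + 1) / sqrt(n) # sd(chi2(3)) = sqrt(6), shift adds a little
  expect_lt(abs(mean(cov$x_ga) - (43 - 3 - 0.5 * 0.05)), 4 * se_ga)
})

test_that("zero correlation decouples the exposures without touching margins", {
  n <- 1e5
  cov <- draw_covariates(small_config(n = n, rho = 0))
  expect_lt(abs(cor(cov$x1, cov$x2)), 4 / sqrt(n))
  expect_lt(abs(var(cov$x2) - 1), 4 * sqrt(2 / n))
})

test_that("invalid correlation is rejected at configuration time", {
  expect_error(scenario_config(rho = 1), "rho")
  expect_error(scenario_config(rho = -1.2), "rho")
  expect_error(scenario_config(sigma2_w1 = -0.1), "sigma2_w1")
})

test_that("classical measurement error has the stated variance and is independent of truth", {
  n <- 2e5
  x <- withr::with_seed(7L, rnorm(n))

  expect_identical(add_measurement_error(x, 0), x)

  w <- add_measurement_error(x, 0.25, seed = 99L)
  expect_lt(abs(var(w) - 1.25), 4 * 1.25 * sqrt(2 / n))
  expect_lt(abs(cor(w - x, x)), 4 / sqrt(n))

  expect_error(add_measurement_error(x, -1), "non-negative")
})

test_that("rounding operator rounds ties away from zero and flags out-of-range values", {
  rt <- round_truncate(c(24.4, 22.4, 43.5), 23, 43)
  expect_identical(rt$value, c(24L, 22L, 44L))
  expect_identical(rt$keep, c(TRUE, FALSE, FALSE))

  # exhaustive half-integer grid oracle: ties away from zero means x + 0.5
  half <- seq(22.5, 43.5, by = 1)
  rt <- round_truncate(half, 23, 43)
  expect_identical(rt$value, as.integer(half + 0.5))
  expect_identical(rt$keep, (half + 0.5) >= 23 & (half + 0.5) <= 43)

  # negative ties go away from zero too
  expect_identical(round_truncate(c(-0.5, 0.5), -2, 2)$value, c(-1L, 1L))

  # completed-weeks mode floors instead
  expect_identical(round_truncate(c(24.9, 43.5), 23, 43, mode = "floor")$value,
                   c(24L, 43L))
  expect_error(round_truncate(1, 5, 5), "lo < hi")
})

test_that("latent outcome follows the branch formulas exactly when noise is suppressed", {
  cfg <- small_config(beta1 = 0.4, beta3 = 1, beta4 = 0.1)
  cov <- tibble::tibble(
    x1 = c(-3, -2, -1.5, 0, 1, 2),
    x2 = 0, z = 0L, x_ga = 40, shifted = 0L
  )

  y_lin <- compute_latent_outcome(cov, "linear", cfg, eps_y = 0)
  expect_equal(y_lin[5] - y_lin[4], 0.4) # slope beta1 by construction

  # fix the inflection at -1 to probe the branches deterministically
  y_thr <- compute_latent_outcome(cov, "threshold", cfg, eps_y = 0, inflection = -1)
  expect_equal(y_thr[1], y_thr[3]) # flat below the inflection point
  expect_equal(y_thr[6] - y_thr[5], 1.5 * 0.4) # slope 1.5 * beta1 above

  y_sat <- compute_latent_outcome(cov, "saturation", cfg, eps_y = 0, inflection = -1)
  slope_below <- (y_sat[2] - y_sat[1]) / 1
  slope_above <- (y_sat[6] - y_sat[5]) / 1
  expect_equal(slope_below / slope_above, 3) # effect three times greater below

  expect_error(compute_latent_outcome(cov, "quadratic", cfg), "shape")
})

test_that("severity transform yields in-range integers and preserves latent ranking", {
  coh <- build_cohort(small_config(n = 2e4))
  expect_true(all(coh$aosi == as.integer(coh$aosi)))
  expect_true(all(coh$aosi >= 0 & coh$aosi <= 18))
  expect_identical(coh$case, as.integer(coh$aosi >= 7))

  # monotone map + rounding can only create ties, never inversions
  ord <- order(coh$y_latent)
  expect_true(all(diff(coh$aosi[ord]) >= 0))
  expect_gt(cor(coh$y_latent, coh$aosi, method = "spearman"), 0.95)
})

test_that("default severity transform gives a plausible case prevalence", {
  coh <- build_cohort(small_config(n = 5e4, shape = "linear", beta1 = 0.15,
                                   sigma2_w1 = 0))
  prev <- mean(coh$case)
  expect_gt(prev, 0.05)
  expect_lt(prev, 0.5)
})

test_that("cohort builder enforces size, inclusion bounds and determinism", {
  cfg <- small_config(n = 4000)
  coh <- build_cohort(cfg)
  expect_identical(nrow(coh), 4000L)
  expect_true(all(coh$w_ga >= 23L & coh$w_ga <= 43L))
  expect_false(anyNA(coh))

  expect_identical(
    as.data.frame(build_cohort(cfg)),
    as.data.frame(coh)
  )
  coh2 <- build_cohort(small_config(n = 4000, seed = 43L))
  expect_false(isTRUE(all.equal(coh$x1, coh2$x1)))
})

test_that("without measurement error the observed exposures equal the true ones", {
  coh <- build_cohort(small_config(sigma2_w1 = 0, sigma2_w2 = 0))
  expect_identical(coh$w1, coh$x1)
  expect_identical(coh$w2, coh$x2)
})

test_that("cohorts differing only in error variance share their covariate draws", {
  a <- build_cohort(small_config(sigma2_w1 = 0.0625))
  b <- build_cohort(small_config(sigma2_w1 = 1))
  expect_identical(a$x1, b$x1)
  expect_identical(a$w_ga, b$w_ga)
  expect_identical(a$y_latent, b$y_latent)
  # and the error draws are the same standard-normal stream, rescaled
  expect_equal((b$w1 - b$x1) / 4, (a$w1 - a$x1) / 1, tolerance = 1e-12)
})

test_that("error attenuates the truth-observation correlation as 1/sqrt(1+sigma2)", {
  n <- 2e5
  for (s2 in c(0.25, 1)) {
    coh <- build_cohort(small_config(n = n, sigma2_w1 = s2))
    expect_lt(abs(cor(coh$w1, coh$x1) - 1 / sqrt(1 + s2)), 0.005)
  }
})

test_that("the non-causal exposure is conditionally unrelated to the outcome", {
  coh <- build_cohort(small_config(n = 2e5, shape = "linear", beta1 = 0.5))
  r_y <- resid(lm(y_latent ~ x1, data = coh))
  r_x2 <- resid(lm(x2 ~ x1, data = coh))
  expect_lt(abs(cor(r_y, r_x2)), 4 / sqrt(nrow(coh)))
})

test_that("a pathological gestational-age error variance aborts with a diagnostic", {
  # with an error SD of 100 weeks almost no rounded value lands in [23, 43]
  expect_error(
    build_cohort(small_config(n = 1000, sigma2_ga = 1e4)),
    "inclusion criterion"
  )
})

test_that("cohort CSV round-trip preserves values and column order", {
  coh <- build_cohort(small_config(n = 500))
  path <- file.path(withr::local_tempdir(), "cohort.csv.gz")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_identical(
    names(back),
    c("x1", "x2", "z", "x_ga", "w1", "w2", "w_ga", "y_latent", "aosi", "case")
  )
  expect_equal(back$w1, coh$w1, tolerance = 1e-12)
  expect_identical(back$aosi, coh$aosi)
})

test_that("scenario YAML round-trip and overrides work", {
  cfg <- small_config(shape = "saturation", beta1 = 0.25)
  path <- file.path(withr::local_tempdir(), "config.yaml")
  scenario_to_yaml(cfg, path)
  cfg2 <- scenario_from_yaml(path)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  cfg3 <- scenario_from_yaml(path, overrides = list(n = 123L, sigma2_w1 = 1))
  expect_identical(cfg3$n, 123L)
  expect_identical(cfg3$sigma2_w1, 1)
  expect_identical(cfg3$shape, "saturation")
  writeLines("nonsense_field: 1", path)
  expect_error(scenario_from_yaml(path), "Unknown config fields")
})
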