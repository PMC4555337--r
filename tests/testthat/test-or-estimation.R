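test_that("pattern collapsing conserves counts and matches a direct tally", {
  coh <- build_cohort(small_config(n = 2000))
  expo <- dichotomize(coh$w1, 0)
  cells <- collapse_to_patterns(coh, expo)
  expect_identical(sum(cells$n), nrow(coh))
  expect_lte(nrow(cells), 32L) # 2^4 covariate patterns x 2 outcomes

  # independent tally with dplyr on the raw rows
  ref <- dplyr::count(
    tibble::tibble(
      exposure = expo,
      w2c = as.integer(coh$w2 >= 1),
      z = coh$z,
      wgac = as.integer(coh$w_ga >= 37),
      case = coh$case
    ),
    exposure, w2c, z, wgac, case
  )
  ref <- dplyr::arrange(ref, exposure, w2c, z, wgac, case)
  got <- dplyr::arrange(cells, exposure, w2c, z, wgac, case)
  expect_equal(as.data.frame(got), as.data.frame(ref))
})

test_that("collapsed-count fit reproduces the row-level logistic fit", {
  coh <- build_cohort(small_config(n = 1000, beta1 = 0.5, sigma2_w1 = 0.25))
  expo <- dichotomize(coh$w1, 0)
  fit <- fit_logistic(collapse_to_patterns(coh, expo))

  rows <- data.frame(
    case = coh$case,
    exposure = expo,
    w2c = as.integer(coh$w2 >= 1),
    z = coh$z,
    wgac = as.integer(coh$w_ga >= 37)
  )
  ref <- glm(case ~ exposure + w2c + z + wgac, family = binomial(), data = rows)
  expect_equal(fit$coefficients, coef(ref), tolerance = 1e-7)
  expect_equal(fit$or1, exp(coef(ref)[["exposure"]]), tolerance = 1e-7)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("with constant adjustment covariates the OR is the 2x2 cross-product ratio", {
  # a = 30 exposed cases, b = 20 exposed controls,
  # c = 10 unexposed cases, d = 40 unexposed controls -> OR = ad/bc = 6
  coh <- toy_cohort(
    x1 = rep(c(1, 1, -1, -1), times = c(30, 20, 10, 40)),
    w1 = rep(c(1, 1, -1, -1), times = c(30, 20, 10, 40)),
    case = rep(c(1, 0, 1, 0), times = c(30, 20, 10, 40))
  )
  fit <- fit_logistic(collapse_to_patterns(coh, dichotomize(coh$w1, 0)))
  expect_equal(fit$or1, (30 * 40) / (20 * 10), tolerance = 1e-8)
  expect_identical(fit$n_exposed_cases, 30L)
})

test_that("an exposure independent of the outcome yields an OR near one", {
  coh <- build_cohort(small_config(n = 2e4, beta1 = 0.5))
  coh$case <- withr::with_seed(8L, sample(coh$case)) # break the association
  fit <- fit_logistic(collapse_to_patterns(coh, dichotomize(coh$w1, 0)))
  expect_gt(fit$or$ci_hi[1], 1)
  expect_lt(fit$or$ci_lo[1], 1)
})

test_that("degenerate cells are flagged, not thrown", {
  # zero exposed cases: separation, OR reported missing
  coh <- toy_cohort(
    x1 = rep(c(1, -1, -1), times = c(20, 15, 40)),
    w1 = rep(c(1, -1, -1), times = c(20, 15, 40)),
    case = rep(c(0, 1, 0), times = c(20, 15, 40))
  )
  fit <- fit_logistic(collapse_to_patterns(coh, dichotomize(coh$w1, 0)))
  expect_true(fit$separation)
  expect_true(is.na(fit$or1))

  # all-zero exposure column: exposure collapses out entirely
  fit0 <- fit_logistic(collapse_to_patterns(coh, rep(0L, nrow(coh))))
  expect_true(fit0$separation)
  expect_true(is.na(fit0$or1))

  # single outcome class
  coh$case <- 0L
  fit1 <- fit_logistic(collapse_to_patterns(coh, dichotomize(coh$w1, 0)))
  expect_true(fit1$separation)
  expect_true(is.na(fit1$or1))
})

test_that("the OR curve has one point per cutoff and never aborts", {
  coh <- build_cohort(small_config(n = 5000, beta1 = 0.5))
  curve <- build_or_curve(coh)
  expect_identical(nrow(curve), 61L)
  expect_true(!is.unsorted(curve$phi, strictly = TRUE))
  # extreme cutoffs on 5000 subjects will separate; flagged, not errored
  expect_true(all(is.na(curve$or) | curve$or > 0))
})

test_that("with no exposure error the observed and true curves coincide", {
  coh <- build_cohort(small_config(n = 5000, sigma2_w1 = 0))
  g <- make_dichotomy_grid(-2, 2, 0.5)
  cw <- build_or_curve(coh, g, "observed")
  cx <- build_or_curve(coh, g, "true")
  expect_equal(cw$or, cx$or, tolerance = 1e-12)
  expect_equal(cw$phi_raw, cx$phi_raw, tolerance = 1e-12)
})

test_that("category table reports four contrasts per width", {
  coh <- build_cohort(small_config(n = 2e4, beta1 = 0.5))
  tab <- build_category_table(coh, delta_values = c(0.5, 1, 1.5))
  expect_identical(nrow(tab), 12L)
  expect_identical(unique(tab$category), c(1L, 2L, 4L, 5L))
  expect_error(build_category_table(coh, delta_values = c(1, -1)), "positive")
})

test_that("under the global null all category ORs sit near one", {
  coh <- build_cohort(small_config(n = 1e5, beta1 = 0, sigma2_w1 = 0.25))
  tab <- build_category_table(coh, delta_values = c(0.5, 1, 1.5))
  # every log-OR within 4.5 standard errors of zero (SE backed out of the CI),
  # and the bulk of the table close to the null in absolute terms
  se <- (log(tab$ci_hi) - log(tab$ci_lo)) / (2 * 1.96)
  expect_true(all(abs(log(tab$or)) < 4.5 * se))
  expect_lt(median(abs(log(tab$or))), 0.05)
})

test_that("the linear no-error model shows a monotone dose-response across categories", {
  coh <- build_cohort(small_config(n = 1e5, beta1 = 0.5, sigma2_w1 = 0))
  tab <- build_category_table(coh, delta_values = 1)
  ors <- setNames(tab$or, tab$category)
  expect_gt(ors[["5"]], ors[["4"]])
  expect_gt(ors[["4"]], 1)
  expect_lt(ors[["2"]], 1)
  expect_lt(ors[["1"]], ors[["2"]])
})
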