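# Shared fixtures and independent oracles used across the test files.

small_config <- function(...) {
  args <- utils::modifyList(list(n = 5000L, seed = 42L), list(...))
  do.call(scenario_config, args)
}

# Quadrature oracles over the joint Gaussian of (X, W = X + eps),
# X ~ N(0,1), eps ~ N(0, sigma2): classification accuracy of thresholding W
# at t when the truth is X >= phi. Independent of the counting code.
oracle_prob_w_ge <- function(t, phi, sigma2, truth_exposed = TRUE) {
  se <- sqrt(sigma2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((t - x) / se, lower.tail = FALSE)
  if (truth_exposed) {
    stats::integrate(f, phi, Inf, rel.tol = 1e-10)$value /
      stats::pnorm(phi, lower.tail = FALSE)
  } else {
    stats::integrate(f, -Inf, phi, rel.tol = 1e-10)$value / stats::pnorm(phi)
  }
}

oracle_sensitivity <- function(phi, sigma2) oracle_prob_w_ge(phi, phi, sigma2, TRUE)
oracle_specificity <- function(phi, sigma2) 1 - oracle_prob_w_ge(phi, phi, sigma2, FALSE)

# Minimal cohort-shaped tibble for unit tests that bypass the generator.
toy_cohort <- function(x1, w1, case = 0L, w2 = 0, z = 0L, w_ga = 40L) {
  tibble::tibble(
    x1 = x1, w1 = w1,
    w2 = rep_len(w2, length(x1)),
    z = rep_len(as.integer(z), length(x1)),
    w_ga = rep_len(as.integer(w_ga), length(x1)),
    case = rep_len(as.integer(case), length(x1))
  )
}
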