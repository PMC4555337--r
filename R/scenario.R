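#' Scenario configuration for the simulated cohort
#'
#' Bundles every knob of the data-generating process: the exposure-response
#' shape, regression coefficients of the latent outcome model, measurement
#' error variances, the exposure correlation, cohort size, gestational-age
#' and severity-score bounds, the case-defining cutoff, the parameters of the
#' lognormal severity transform, and the master seed.
#'
#' Defaults reproduce the reference study conditions: two correlated
#' standard-normal exposures (rho = 0.7) of which only the first is causal,
#' Bernoulli(0.5) sex, gestational age 43 - chi-squared(3) weeks with a
#' one-week reduction for 5% of males and inclusion restricted to 23-43
#' completed weeks, classical additive Gaussian measurement error, and an
#' integer severity score on 0-18 with cases defined at scores >= 7.
#'
#' @param shape Exposure-response shape of the latent outcome model: one of
#'   `"linear"`, `"threshold"` (no effect below the inflection point, slope
#'   `1.5 * beta1` above it) or `"saturation"` (slope `1.5 * beta1` below the
#'   inflection point, `0.5 * beta1` above it). The inflection point is
#'   `mean(x1) - sd(x1)` computed from the realized cohort.
#' @param beta1 Effect of the causal exposure X1 on the latent outcome;
#'   0.15, 0.25 and 0.5 correspond to weak, moderate and strong associations.
#' @param beta2 Effect of the non-causal exposure X2 (0: no true effect).
#' @param beta3 Effect of male sex.
#' @param beta4 Effect of gestational age, per week.
#' @param sigma2_w1 Variance of the classical measurement error on X1;
#'   0 means the exposure is observed perfectly. The study grid uses
#'   0, 0.0625, 0.25 and 1.
#' @param sigma2_w2 Variance of the measurement error on X2.
#' @param sigma2_ga Variance of the continuous gestational-age error, in
#'   weeks squared. Default `(1/7)^2`, i.e. a one-day reporting error.
#' @param rho Pearson correlation between the true exposures X1 and X2;
#'   must lie strictly inside (-1, 1).
#' @param n Cohort size after the gestational-age inclusion criterion.
#' @param male_prob Probability that a subject is male.
#' @param male_shift_frac Fraction of males whose gestational age is reduced
#'   by one week (shortened gestation among boys).
#' @param ga_bounds Integer pair: inclusive bounds, in completed weeks, for
#'   the observed gestational age; subjects outside are excluded.
#' @param aosi_bounds Integer pair: valid range of the severity score.
#' @param case_cutoff Severity score at or above which a subject is a case.
#' @param aosi_mu_log,aosi_sigma_log Location and scale, on the log scale, of
#'   the monotone lognormal map from the standardized latent outcome to the
#'   severity score.
#' @param round_mode Rounding rule for the week/score rounding operator:
#'   `"half_away"` rounds to the nearest integer with ties away from zero;
#'   `"floor"` keeps completed weeks.
#' @param seed Master seed; every random stream of the generator is derived
#'   from it deterministically.
#'
#' @return An object of class `scenario_config` (a named list).
#' @seealso [build_cohort()], [scenario_from_yaml()]
#' @examples
#' cfg <- scenario_config(shape = "linear", beta1 = 0.5, n = 1000, seed = 7)
#' cfg$sigma2_w1
#' @export
scenario_config <- function(shape = c("linear", "threshold", "saturation"),
                            beta1 = 0.5,
                            beta2 = 0,
                            beta3 = 1,
                            beta4 = 0.1,
                            sigma2_w1 = 0.25,
                            sigma2_w2 = 0.25,
                            sigma2_ga = (1 / 7)^2,
                            rho = 0.7,
                            n = 1e6,
                            male_prob = 0.5,
                            male_shift_frac = 0.05,
                            ga_bounds = c(23L, 43L),
                            aosi_bounds = c(0L, 18L),
                            case_cutoff = 7L,
                            aosi_mu_log = 1.3,
                            aosi_sigma_log = 0.6,
                            round_mode = c("half_away", "floor"),
                            seed = 1L) {
  shape <- match.arg(shape)
  round_mode <- match.arg(round_mode)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= -1 || rho >= 1) {
    stop("`rho` must be a single number strictly inside (-1, 1).", call. = FALSE)
  }
  for (nm in c("sigma2_w1", "sigma2_w2", "sigma2_ga")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative number.", call. = FALSE)
    }
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be a positive integer.", call. = FALSE)
  ga_bounds <- as.integer(ga_bounds)
  aosi_bounds <- as.integer(aosi_bounds)
  if (length(ga_bounds) != 2 || ga_bounds[1] >= ga_bounds[2]) {
    stop("`ga_bounds` must be an increasing integer pair.", call. = FALSE)
  }
  if (length(aosi_bounds) != 2 || aosi_bounds[1] >= aosi_bounds[2]) {
    stop("`aosi_bounds` must be an increasing integer pair.", call. = FALSE)
  }
  case_cutoff <- as.integer(case_cutoff)
  if (case_cutoff < aosi_bounds[1] || case_cutoff > aosi_bounds[2]) {
    stop("`case_cutoff` must lie within `aosi_bounds`.", call. = FALSE)
  }
  if (!is.numeric(male_prob) || male_prob < 0 || male_prob > 1 ||
      !is.numeric(male_shift_frac) || male_shift_frac < 0 || male_shift_frac > 1) {
    stop("`male_prob` and `male_shift_frac` must be probabilities.", call. = FALSE)
  }
  structure(
    list(
      shape = shape, beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
      sigma2_w1 = sigma2_w1, sigma2_w2 = sigma2_w2, sigma2_ga = sigma2_ga,
      rho = rho, n = n, male_prob = male_prob, male_shift_frac = male_shift_frac,
      ga_bounds = ga_bounds, aosi_bounds = aosi_bounds, case_cutoff = case_cutoff,
      aosi_mu_log = aosi_mu_log, aosi_sigma_log = aosi_sigma_log,
      round_mode = round_mode, seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  shape: %s   beta1: %g   sigma2_w1: %g\n",
              x$shape, x$beta1, x$sigma2_w1))
  cat(sprintf("  n: %s   rho: %g   seed: %d\n",
              format(x$n, big.mark = ","), x$rho, x$seed))
  cat(sprintf("  case: severity >= %d on [%d, %d]\n",
              x$case_cutoff, x$aosi_bounds[1], x$aosi_bounds[2]))
  invisible(x)
}

#' Read or write a scenario configuration as YAML
#'
#' The YAML file mirrors the field names of [scenario_config()]; missing
#' fields fall back to the defaults. `overrides` (a named list) takes
#' precedence over the file, which is how command-line flags such as `--n`
#' or `--sigma2` are applied.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of fields overriding the file contents.
#' @return `scenario_from_yaml()` returns a `scenario_config`;
#'   `scenario_to_yaml()` writes the file and returns `path` invisibly.
#' @export
scenario_from_yaml <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("Config file must contain a YAML mapping.", call. = FALSE)
  raw <- utils::modifyList(raw, overrides)
  known <- names(formals(scenario_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("Unknown config fields: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(scenario_config, raw)
}

#' @rdname scenario_from_yaml
#' @param config A `scenario_config`.
#' @export
scenario_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
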