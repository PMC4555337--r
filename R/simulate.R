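# Random streams -------------------------------------------------------------

# Named, independent substreams derived from the master seed so that changing
# one part of the generator (e.g. the exposure error variance) never perturbs
# the draws of another. Stream seeds are a fixed affine hash of (stream, batch)
# folded into the 31-bit range set.seed() accepts.
.streams <- c(
  covariates = 1L, sex = 2L, shift = 3L, ga = 4L,
  eps_ga = 5L, eps1 = 6L, eps2 = 7L, eps_y = 8L
)

stream_seed <- function(seed, stream, batch = 1L) {
  off <- .streams[[stream]]
  s <- (as.double(seed) + 1000003 * off + 7919 * (as.double(batch) - 1)) %%
    (.Machine$integer.max - 1)
  as.integer(s) + 1L
}

#' Draw the true covariates of the simulated cohort
#'
#' Generates `n` records of the true (error-free) covariates: a bivariate
#' standard-normal exposure pair with correlation `rho`, Bernoulli sex, and
#' gestational age `43 - gamma` weeks where `gamma ~ chi-squared(3)`, with a
#' further one-week reduction for a random `male_shift_frac` fraction of
#' males. No inclusion criterion is applied here; see [build_cohort()].
#'
#' @param config A [scenario_config()].
#' @param n Number of records to draw (default `config$n`).
#' @param batch Internal batch index; advances the random streams when
#'   [build_cohort()] needs to redraw excluded subjects.
#' @return A tibble with columns `x1`, `x2` (true exposures), `z` (1 = male),
#'   `x_ga` (true gestational age, weeks) and `shifted` (1 = male who
#'   received the one-week reduction).
#' @examples
#' cov <- draw_covariates(scenario_config(n = 1000, seed = 1))
#' cor(cov$x1, cov$x2)
#' @export
draw_covariates <- function(config, n = config$n, batch = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  rho <- config$rho
  xs <- withr::with_seed(stream_seed(config$seed, "covariates", batch), {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    list(x1 = z1, x2 = rho * z1 + sqrt(1 - rho^2) * z2)
  })
  z <- withr::with_seed(
    stream_seed(config$seed, "sex", batch),
    stats::rbinom(n, 1L, config$male_prob)
  )
  shifted <- withr::with_seed(
    stream_seed(config$seed, "shift", batch),
    as.integer(z == 1L & stats::runif(n) < config$male_shift_frac)
  )
  gamma <- withr::with_seed(
    stream_seed(config$seed, "ga", batch),
    stats::rchisq(n, df = 3)
  )
  tibble::tibble(
    x1 = xs$x1,
    x2 = xs$x2,
    z = z,
    x_ga = config$ga_bounds[2] - gamma - shifted,
    shifted = shifted
  )
}

#' Contaminate a vector with classical measurement error
#'
#' Adds independent `N(0, sigma2)` noise to `values` (W = X + eps). With
#' `sigma2 = 0` the input is returned unchanged. The error draws are
#' independent of the input and, when a dedicated `seed` is supplied, of
#' every other stream.
#'
#' @param values Numeric vector of true values.
#' @param sigma2 Error variance (non-negative).
#' @param seed Optional seed for a dedicated error stream; when `NULL` the
#'   current RNG state is used.
#' @param z Optional pre-drawn standard-normal vector, scaled by
#'   `sqrt(sigma2)`; used by [build_cohort()] so that cohorts differing only
#'   in `sigma2` share the same underlying error draws (paired comparisons).
#' @return Numeric vector of observed values.
#' @export
add_measurement_error <- function(values, sigma2, seed = NULL, z = NULL) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || is.na(sigma2) || sigma2 < 0) {
    stop("`sigma2` must be a single non-negative number.", call. = FALSE)
  }
  if (sigma2 == 0) return(values)
  if (is.null(z)) {
    z <- if (is.null(seed)) {
      stats::rnorm(length(values))
    } else {
      withr::with_seed(seed, stats::rnorm(length(values)))
    }
  }
  stopifnot(length(z) == length(values))
  values + sqrt(sigma2) * z
}

#' Round to integers and flag values inside closed bounds
#'
#' The rounding/truncation operator applied to observed gestational age and
#' to the severity score: rounds each value to an integer and marks whether
#' the rounded value falls inside `[lo, hi]`. "Truncation" here means
#' retention — values outside the interval are flagged for exclusion, not
#' clipped.
#'
#' @param values Numeric vector.
#' @param lo,hi Integer bounds, `lo < hi`.
#' @param mode `"half_away"` (round to nearest, ties away from zero) or
#'   `"floor"` (completed units).
#' @return A list with `value` (integer vector) and `keep` (logical vector,
#'   `TRUE` when the rounded value lies in `[lo, hi]`).
#' @examples
#' round_truncate(c(24.4, 22.4, 43.5), 23, 43)
#' @export
round_truncate <- function(values, lo, hi, mode = c("half_away", "floor")) {
  mode <- match.arg(mode)
  stopifnot(lo < hi)
  r <- switch(mode,
    half_away = sign(values) * floor(abs(values) + 0.5),
    floor = floor(values)
  )
  list(value = as.integer(r), keep = r >= lo & r <= hi)
}

#' Latent outcome under the linear, threshold or saturation model
#'
#' Evaluates the latent continuous outcome for each subject:
#' \describe{
#'   \item{linear}{`y = beta1*x1 + beta2*x2 + beta3*z + beta4*x_ga + eps_y`}
#'   \item{threshold}{no exposure effect below the inflection point;
#'     slope `1.5 * beta1` at or above it}
#'   \item{saturation}{slope `1.5 * beta1` below the inflection point;
#'     slope `0.5 * beta1` at or above it (effect three times greater below)}
#' }
#' The inflection point defaults to `mean(x1) - sd(x1)` of the supplied
#' covariate table (approximately -1 for a standard-normal exposure). The
#' piecewise formulas are applied exactly as stated, including the implied
#' discontinuity of the fitted mean at the inflection point.
#'
#' @param cov Covariate table from [draw_covariates()].
#' @param shape One of `"linear"`, `"threshold"`, `"saturation"`.
#' @param config A [scenario_config()] supplying the betas.
#' @param eps_y Optional noise vector; defaults to fresh `N(0, 1)` draws from
#'   the outcome stream. Pass `0` to evaluate the noiseless branch formulas.
#' @param inflection Optional override of the inflection point.
#' @return Numeric vector of latent outcomes with attribute `"inflection"`.
#' @export
compute_latent_outcome <- function(cov, shape = config$shape, config,
                                   eps_y = NULL, inflection = NULL) {
  if (!shape %in% c("linear", "threshold", "saturation")) {
    stop("Unknown model shape: ", shape, call. = FALSE)
  }
  n <- nrow(cov)
  if (is.null(eps_y)) {
    eps_y <- withr::with_seed(
      stream_seed(config$seed, "eps_y"),
      stats::rnorm(n)
    )
  } else if (length(eps_y) == 1) {
    eps_y <- rep(eps_y, n)
  }
  if (is.null(inflection)) inflection <- mean(cov$x1) - stats::sd(cov$x1)
  base <- config$beta2 * cov$x2 + config$beta3 * cov$z + config$beta4 * cov$x_ga + eps_y
  b1 <- config$beta1
  y <- switch(shape,
    linear = b1 * cov$x1 + base,
    threshold = ifelse(cov$x1 < inflection, base, 1.5 * b1 * cov$x1 + base),
    saturation = ifelse(cov$x1 < inflection,
                        1.5 * b1 * cov$x1 + base,
                        0.5 * b1 * cov$x1 + base)
  )
  attr(y, "inflection") <- inflection
  y
}

#' Map the latent outcome to an integer severity score
#'
#' Applies a strictly monotone lognormal-style transform to the latent
#' outcome — `exp(mu_log + sigma_log * standardize(y))` — then rounds to an
#' integer and clamps to the valid score range (0-18 by default). Rounding
#' can create ties but never inversions, so the score preserves the ranking
#' of the latent outcome. The transform is a configurable stand-in for an
#' empirical severity-score distribution, not a reproduction of any
#' particular instrument's data.
#'
#' @param y Numeric vector of latent outcomes.
#' @param config A [scenario_config()] supplying `aosi_mu_log`,
#'   `aosi_sigma_log`, `aosi_bounds` and the rounding mode.
#' @return Integer vector of severity scores within `config$aosi_bounds`.
#' @export
transform_to_aosi <- function(y, config) {
  s <- (y - mean(y)) / stats::sd(y)
  raw <- exp(config$aosi_mu_log + config$aosi_sigma_log * s)
  r <- round_truncate(raw, config$aosi_bounds[1], config$aosi_bounds[2],
                      mode = config$round_mode)
  # Scores outside the instrument range are clamped, not excluded: exclusion
  # would silently shrink the cohort below n.
  as.integer(pmin(pmax(r$value, config$aosi_bounds[1]), config$aosi_bounds[2]))
}

#' Build the full simulated cohort
#'
#' Chains the generator end to end: draws true covariates, contaminates the
#' exposures and gestational age with classical error, rounds gestational
#' age to completed weeks, excludes subjects outside the inclusion bounds
#' (redrawing until exactly `n` subjects are retained), evaluates the latent
#' outcome under the configured shape, and derives the severity score and
#' case indicator. The whole pipeline is deterministic given `config$seed`,
#' and cohorts differing only in `sigma2_w1` share their covariate and
#' error-stream draws, so error-variance comparisons are paired.
#'
#' @param config A [scenario_config()].
#' @return A tibble of class `cohort` with `n` rows and columns
#'   `x1, x2, z, x_ga` (true values), `w1, w2, w_ga` (observed values),
#'   `y_latent`, `aosi`, `case`, plus attributes `config` and `inflection`.
#' @examples
#' coh <- build_cohort(scenario_config(n = 2000, seed = 42))
#' table(coh$case)
#' @export
build_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n
  got <- 0L
  batch <- 1L
  parts <- list()
  while (got < n) {
    m <- as.integer(ceiling((n - got) * 1.05) + 100L)
    cov <- draw_covariates(config, n = m, batch = batch)
    z1 <- withr::with_seed(stream_seed(config$seed, "eps1", batch), stats::rnorm(m))
    z2 <- withr::with_seed(stream_seed(config$seed, "eps2", batch), stats::rnorm(m))
    zga <- withr::with_seed(stream_seed(config$seed, "eps_ga", batch), stats::rnorm(m))
    zy <- withr::with_seed(stream_seed(config$seed, "eps_y", batch), stats::rnorm(m))
    w_ga_cont <- add_measurement_error(cov$x_ga, config$sigma2_ga, z = zga)
    rt <- round_truncate(w_ga_cont, config$ga_bounds[1], config$ga_bounds[2],
                         mode = config$round_mode)
    if (mean(rt$keep) < 0.1) {
      stop(sprintf(
        "Pathological configuration: only %.1f%% of subjects satisfy the gestational-age inclusion criterion [%d, %d].",
        100 * mean(rt$keep), config$ga_bounds[1], config$ga_bounds[2]
      ), call. = FALSE)
    }
    part <- cov
    part$w_ga <- rt$value
    part$.z1 <- z1
    part$.z2 <- z2
    part$.zy <- zy
    parts[[batch]] <- part[rt$keep, , drop = FALSE]
    got <- got + sum(rt$keep)
    batch <- batch + 1L
  }
  base <- dplyr::bind_rows(parts)[seq_len(n), , drop = FALSE]

  w1 <- add_measurement_error(base$x1, config$sigma2_w1, z = base$.z1)
  w2 <- add_measurement_error(base$x2, config$sigma2_w2, z = base$.z2)
  y <- compute_latent_outcome(base, config$shape, config, eps_y = base$.zy)
  aosi <- transform_to_aosi(y, config)

  out <- tibble::tibble(
    x1 = base$x1, x2 = base$x2, z = base$z, x_ga = base$x_ga,
    w1 = w1, w2 = w2, w_ga = base$w_ga,
    y_latent = as.numeric(y), aosi = aosi,
    case = as.integer(aosi >= config$case_cutoff)
  )
  attr(out, "config") <- config
  attr(out, "inflection") <- attr(y, "inflection")
  class(out) <- c("cohort", class(out))
  out
}

#' Write or read a cohort as (optionally gzip-compressed) CSV
#'
#' Columns are written in the fixed order
#' `x1, x2, z, x_ga, w1, w2, w_ga, y_latent, aosi, case`. A `.gz` extension
#' triggers gzip compression.
#'
#' @param cohort A cohort tibble from [build_cohort()].
#' @param path Output (input) file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("x1", "x2", "z", "x_ga", "w1", "w2", "w_ga", "y_latent", "aosi", "case")
  readr::write_csv(as.data.frame(cohort)[, cols], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      x1 = "d", x2 = "d", z = "i", x_ga = "d", w1 = "d", w2 = "d",
      w_ga = "i", y_latent = "d", aosi = "i", case = "i"
    )
  )
}
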