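# Adjustment covariates are fixed dichotomizations of the non-causal
# exposure (< 1 vs >= 1) and observed gestational age (< 37 vs >= 37 weeks,
# the preterm/term boundary), with the boundary on the indicator-1 side in
# both cases, matching the exposure convention.
.adjustment_covariates <- function(cohort) {
  list(
    w2c = as.integer(cohort$w2 >= 1),
    z = as.integer(cohort$z),
    wgac = as.integer(cohort$w_ga >= 37)
  )
}

#' Collapse a cohort to covariate-pattern counts
#'
#' With an all-categorical design the logistic likelihood depends on the
#' data only through the counts of each covariate pattern by outcome, so a
#' million-row cohort collapses to at most `levels(exposure) * 16` rows
#' (16 for a dichotomous exposure). Fitting on the collapsed counts with
#' prior weights reproduces the row-level fit exactly.
#'
#' @param cohort A cohort tibble (needs `w2`, `z`, `w_ga`, `case`).
#' @param exposure Integer vector: the coded exposure per subject, either
#'   0/1 from [dichotomize()] or 1..5 from [assign_category()].
#' @return A tibble with columns `exposure`, `w2c`, `z`, `wgac`, `case`, `n`;
#'   `sum(n)` equals the cohort size.
#' @export
collapse_to_patterns <- function(cohort, exposure) {
  stopifnot(length(exposure) == nrow(cohort))
  adj <- .adjustment_covariates(cohort)
  lev <- sort(unique(exposure))
  nl <- length(lev)
  ei <- match(exposure, lev) - 1L
  code <- ei + nl * (adj$w2c + 2L * (adj$z + 2L * (adj$wgac + 2L * cohort$case)))
  tab <- tabulate(code + 1L, nbins = nl * 16L)
  idx <- which(tab > 0L) - 1L
  e <- idx %% nl
  r <- idx %/% nl
  tibble::tibble(
    exposure = lev[e + 1L],
    w2c = r %% 2L,
    z = (r %/% 2L) %% 2L,
    wgac = (r %/% 4L) %% 2L,
    case = (r %/% 8L) %% 2L,
    n = tab[tab > 0L]
  )
}

#' Fit the adjusted logistic model on covariate-pattern counts
#'
#' Maximum-likelihood logistic regression of case status on the coded
#' exposure plus the three fixed adjustment covariates,
#' `logit P(case = 1) = c0 + c1*exposure + c2*w2c + c3*z + c4*wgac`,
#' fitted on collapsed counts via prior weights. A dichotomous exposure
#' enters as a 0/1 indicator (`exp(c1)` is the exposure odds ratio); a
#' five-level exposure enters as a factor with category 3 as reference,
#' yielding four odds-ratio contrasts. Adjustment covariates that are
#' constant in the data are dropped rather than producing NA coefficients.
#'
#' Degenerate inputs never raise: a single outcome class, or a zero cell in
#' the exposure-by-outcome margin (complete/quasi-complete separation for
#' the affected contrast), set the `separation`/`converged` flags and report
#' the affected odds ratios as `NA` so that curve assembly can continue.
#'
#' @param cells Pattern counts from [collapse_to_patterns()].
#' @return An object of class `logistic_fit`: a list with `coefficients`,
#'   `or` (a tibble of odds ratios and Wald 95% CIs per exposure contrast),
#'   `or1` (the single OR for a dichotomous exposure, else `NA`),
#'   `cell_counts`, `n_exposed_cases`, `converged` and `separation`.
#' @export
fit_logistic <- function(cells) {
  lev <- sort(unique(cells$exposure))
  binary <- all(lev %in% c(0L, 1L))
  xt <- stats::xtabs(n ~ exposure + case, data = cells)
  both_outcomes <- ncol(xt) == 2L
  # zero exposure-by-outcome margin cell => the corresponding log-odds
  # contrast is infinite (separation in that direction)
  bad_levels <- if (both_outcomes) rownames(xt)[apply(xt == 0, 1, any)] else as.character(lev)
  separation <- length(bad_levels) > 0 || !both_outcomes || length(lev) < 2L

  dat <- cells
  dat$exposure <- if (binary) {
    dat$exposure
  } else {
    stats::relevel(factor(dat$exposure, levels = lev), ref = "3")
  }
  keep_adj <- vapply(
    c("w2c", "z", "wgac"),
    function(v) length(unique(dat[[v]])) > 1L, logical(1)
  )
  rhs <- c(
    if (length(lev) > 1L) "exposure",
    names(keep_adj)[keep_adj]
  )
  estimable <- both_outcomes && length(lev) > 1L

  coefs <- NULL
  or_tbl <- NULL
  converged <- FALSE
  if (estimable) {
    form <- stats::reformulate(rhs, response = "case")
    fit <- suppressWarnings(
      stats::glm(form, family = stats::binomial(), data = dat, weights = n)
    )
    converged <- isTRUE(fit$converged)
    coefs <- stats::coef(fit)
    sm <- summary(fit)$coefficients
    pick <- grep("^exposure", rownames(sm), value = TRUE)
    est <- sm[pick, "Estimate"]
    se <- sm[pick, "Std. Error"]
    contrast <- if (binary) "1" else sub("^exposure", "", pick)
    or_tbl <- tibble::tibble(
      contrast = contrast,
      or = exp(est),
      ci_lo = exp(est - 1.96 * se),
      ci_hi = exp(est + 1.96 * se)
    )
    # report separated contrasts as missing, not as a huge finite number
    na_mask <- or_tbl$contrast %in% bad_levels | (binary && separation)
    or_tbl$or[na_mask] <- NA_real_
    or_tbl$ci_lo[na_mask] <- NA_real_
    or_tbl$ci_hi[na_mask] <- NA_real_
  } else {
    or_tbl <- tibble::tibble(
      contrast = if (binary) "1" else setdiff(as.character(lev), "3"),
      or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_
    )
  }

  n_exposed_cases <- if (binary) {
    sum(cells$n[cells$exposure == 1L & cells$case == 1L])
  } else {
    NA_integer_
  }

  structure(
    list(
      coefficients = coefs,
      or = or_tbl,
      or1 = if (binary) or_tbl$or[or_tbl$contrast == "1"] else NA_real_,
      cell_counts = cells,
      n_exposed_cases = n_exposed_cases,
      converged = converged,
      separation = separation
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>")
  if (!is.na(x$or1)) cat(sprintf("  OR = %.4f", x$or1))
  cat(sprintf("  converged: %s  separation: %s\n", x$converged, x$separation))
  if (!is.null(x$or) && nrow(x$or) > 1) print(x$or)
  invisible(x)
}

#' Odds-ratio curve across the dichotomization grid
#'
#' Fits one adjusted logistic model per cutoff of the grid, dichotomizing
#' the chosen exposure column at each, and collects the exposure odds
#' ratios. Cutoffs in SD units are anchored at the empirical mean and SD of
#' the exposure column being cut. Per-cutoff separation or non-convergence
#' is recorded in the output flags; the loop never aborts mid-curve.
#'
#' @param cohort A cohort from [build_cohort()].
#' @param grid A [make_dichotomy_grid()] object.
#' @param exposure_source `"observed"` uses the mismeasured exposure `w1`;
#'   `"true"` uses the error-free `x1` (the no-measurement-error reference
#'   model). Adjustment covariates are unchanged.
#' @return A tibble of class `or_curve`: one row per cutoff with `phi`
#'   (grid value), `phi_raw` (raw-scale cutoff), `or`, `ci_lo`, `ci_hi`,
#'   `n_exposed_cases`, `converged`, `separation`.
#' @export
build_or_curve <- function(cohort, grid = make_dichotomy_grid(),
                           exposure_source = c("observed", "true")) {
  exposure_source <- match.arg(exposure_source)
  if (length(grid) == 0) stop("Empty cutoff grid.", call. = FALSE)
  w <- if (exposure_source == "observed") cohort$w1 else cohort$x1
  phi_raw <- if (identical(attr(grid, "scale"), "raw")) {
    as.numeric(grid)
  } else {
    mean(w) + as.numeric(grid) * stats::sd(w)
  }
  rows <- lapply(seq_along(phi_raw), function(i) {
    fit <- fit_logistic(collapse_to_patterns(cohort, dichotomize(w, phi_raw[i])))
    tibble::tibble(
      phi = as.numeric(grid)[i],
      phi_raw = phi_raw[i],
      or = fit$or1,
      ci_lo = fit$or$ci_lo[fit$or$contrast == "1"],
      ci_hi = fit$or$ci_hi[fit$or$contrast == "1"],
      n_exposed_cases = fit$n_exposed_cases,
      converged = fit$converged,
      separation = fit$separation
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "exposure_source") <- exposure_source
  class(out) <- c("or_curve", class(out))
  out
}

#' Category odds ratios across reference-group widths
#'
#' For each reference-group width `delta` (in SD units), builds the
#' five-category scheme centered on the exposure mean, fits one adjusted
#' logistic model with category 3 as reference, and reports the odds ratios
#' of categories 1, 2, 4 and 5. Empty categories at extreme widths are
#' reported as missing for the affected contrasts.
#'
#' @param cohort A cohort from [build_cohort()].
#' @param delta_values Positive reference-group widths; default 0.5 to 1.5
#'   SD in steps of 0.1.
#' @param exposure_source `"observed"` (`w1`) or `"true"` (`x1`).
#' @return A tibble with columns `delta`, `category`, `or`, `ci_lo`,
#'   `ci_hi`, `converged`, `separation`: four odds-ratio rows per `delta`.
#' @export
build_category_table <- function(cohort, delta_values = seq(0.5, 1.5, by = 0.1),
                                 exposure_source = c("observed", "true")) {
  exposure_source <- match.arg(exposure_source)
  if (any(delta_values <= 0)) stop("All `delta_values` must be positive.", call. = FALSE)
  w <- if (exposure_source == "observed") cohort$w1 else cohort$x1
  m <- mean(w)
  s <- stats::sd(w)
  rows <- lapply(delta_values, function(d) {
    scheme <- make_category_scheme(d, center = m, sd = s)
    cat5 <- assign_category(w, scheme)
    fit <- fit_logistic(collapse_to_patterns(cohort, cat5))
    out <- tibble::tibble(
      delta = d,
      category = c(1L, 2L, 4L, 5L),
      converged = fit$converged,
      separation = fit$separation
    )
    m_idx <- match(as.character(out$category), fit$or$contrast)
    out$or <- fit$or$or[m_idx]
    out$ci_lo <- fit$or$ci_lo[m_idx]
    out$ci_hi <- fit$or$ci_hi[m_idx]
    out[, c("delta", "category", "or", "ci_lo", "ci_hi", "converged", "separation")]
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "exposure_source") <- exposure_source
  out
}
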