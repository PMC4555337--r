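#' Sensitivity and specificity of the dichotomized exposure at one cutoff
#'
#' True exposure status at cutoff `phi` is defined by dichotomizing the
#' error-free exposure (`x1 >= phi`); observed status by dichotomizing the
#' mismeasured exposure (`w1 >= phi`) at the same cutoff. Then, within the
#' requested stratum,
#' \deqn{sensitivity = \frac{\#\ exposed\ on\ both}{\#\ truly\ exposed},\quad
#'       specificity = \frac{\#\ unexposed\ on\ both}{\#\ truly\ unexposed}.}
#' Undefined ratios (empty denominator, 0/0) are reported as `NA` rather
#' than 0 or 1, so instability at extreme cutoffs stays visible.
#'
#' @param cohort A cohort from [build_cohort()] (needs `x1`, `w1`, `case`).
#' @param phi Cutoff on the raw exposure scale.
#' @param group Stratum: `"all"`, `"cases"` or `"controls"`.
#' @return A one-row tibble with `phi`, `group`, `sensitivity`,
#'   `specificity`, `n_true_exposed`, `n_true_unexposed`.
#' @export
sens_spec <- function(cohort, phi, group = c("all", "cases", "controls")) {
  group <- match.arg(group)
  stopifnot(is.finite(phi))
  idx <- switch(group,
    all = rep_len(TRUE, nrow(cohort)),
    cases = cohort$case == 1L,
    controls = cohort$case == 0L
  )
  truth <- cohort$x1[idx] >= phi
  obs <- cohort$w1[idx] >= phi
  n_exp <- sum(truth)
  n_unexp <- sum(!truth)
  tibble::tibble(
    phi = phi,
    group = group,
    sensitivity = if (n_exp > 0) sum(obs & truth) / n_exp else NA_real_,
    specificity = if (n_unexp > 0) sum(!obs & !truth) / n_unexp else NA_real_,
    n_true_exposed = n_exp,
    n_true_unexposed = n_unexp
  )
}

#' Sensitivity/specificity curves over the cutoff grid
#'
#' Evaluates [sens_spec()] at every cutoff of the grid for all three strata
#' (cases, controls, all). Cutoffs in SD units are anchored at the
#' empirical mean and SD of the mismeasured exposure, matching
#' [build_or_curve()].
#'
#' @param cohort A cohort from [build_cohort()].
#' @param grid A [make_dichotomy_grid()] object.
#' @return A tibble with one row per (cutoff, stratum): columns `phi`,
#'   `phi_raw`, `group`, `sensitivity`, `specificity`, `n_true_exposed`,
#'   `n_true_unexposed`.
#' @export
sens_spec_curve <- function(cohort, grid = make_dichotomy_grid()) {
  if (length(grid) == 0) stop("Empty cutoff grid.", call. = FALSE)
  phi_raw <- if (identical(attr(grid, "scale"), "raw")) {
    as.numeric(grid)
  } else {
    mean(cohort$w1) + as.numeric(grid) * stats::sd(cohort$w1)
  }
  rows <- lapply(seq_along(phi_raw), function(i) {
    out <- dplyr::bind_rows(
      sens_spec(cohort, phi_raw[i], "cases"),
      sens_spec(cohort, phi_raw[i], "controls"),
      sens_spec(cohort, phi_raw[i], "all")
    )
    out$phi <- as.numeric(grid)[i]
    out$phi_raw <- phi_raw[i]
    out[, c("phi", "phi_raw", "group", "sensitivity", "specificity",
            "n_true_exposed", "n_true_unexposed")]
  })
  dplyr::bind_rows(rows)
}

#' ROC curve of the mismeasured exposure as a classifier of true exposure
#'
#' Fixes the truth at `x1 >= phi_true` and sweeps a classification
#' threshold on the mismeasured exposure `w1` over `thresholds`, collecting
#' one (1 - specificity, sensitivity) point per threshold. Endpoints (0, 0)
#' and (1, 1) are appended and the area under the curve is computed by the
#' trapezoidal rule.
#'
#' @param cohort A cohort from [build_cohort()].
#' @param phi_true Cutoff (raw scale) defining true exposure on `x1`.
#' @param thresholds Ordered thresholds swept on `w1` (raw scale); defaults
#'   to the default 61-point grid anchored at the moments of `w1`.
#' @return An object of class `roc_curve`: a list with `phi_true`, `points`
#'   (tibble `threshold`, `fpr`, `tpr`, ordered by increasing `fpr`) and
#'   `auc`. Degenerate truth (all subjects on one side of `phi_true`)
#'   yields an empty curve with `auc = NA` and a warning.
#' @export
roc_points <- function(cohort, phi_true, thresholds = NULL) {
  if (is.null(thresholds)) {
    g <- make_dichotomy_grid()
    thresholds <- mean(cohort$w1) + as.numeric(g) * stats::sd(cohort$w1)
  }
  stopifnot(!is.unsorted(thresholds))
  truth <- cohort$x1 >= phi_true
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    warning("Degenerate truth at phi_true = ", phi_true,
            ": all subjects fall in one class; empty ROC curve.")
    return(structure(
      list(phi_true = phi_true,
           points = tibble::tibble(threshold = numeric(), fpr = numeric(),
                                   tpr = numeric()),
           auc = NA_real_),
      class = "roc_curve"
    ))
  }
  tpr <- vapply(thresholds, function(t) sum(cohort$w1 >= t & truth) / n_pos, 0)
  fpr <- vapply(thresholds, function(t) sum(cohort$w1 >= t & !truth) / n_neg, 0)
  pts <- tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  # close the curve at (0,0) and (1,1) for the AUC integral
  xx <- c(0, pts$fpr, 1)
  yy <- c(0, pts$tpr, 1)
  auc <- sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  structure(
    list(phi_true = phi_true, points = pts, auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> truth: x1 >= %g, %d points, AUC = %s\n",
              x$phi_true, nrow(x$points),
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}
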