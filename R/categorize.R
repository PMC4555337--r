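#' Build the grid of dichotomization cutoffs
#'
#' An inclusive arithmetic grid of cutoffs, by default from -3 to +3 in
#' steps of 0.1 (61 cutoffs). Grid points are constructed from integer
#' indices (`lo + k * step`) so there is no cumulative floating-point drift.
#' With `scale = "sd"` the values are interpreted as standard deviations
#' away from the empirical mean of the exposure being cut (the convention
#' used throughout the analysis functions); `scale = "raw"` interprets them
#' as raw exposure values.
#'
#' @param lo,hi Grid endpoints, `lo <= hi`.
#' @param step Positive increment.
#' @param scale `"sd"` (cutoffs in SD units from the mean) or `"raw"`.
#' @return A numeric vector of class `cutoff_grid` with attribute `scale`.
#' @examples
#' length(make_dichotomy_grid()) # 61
#' @export
make_dichotomy_grid <- function(lo = -3, hi = 3, step = 0.1,
                                scale = c("sd", "raw")) {
  scale <- match.arg(scale)
  if (!is.numeric(step) || step <= 0) stop("`step` must be positive.", call. = FALSE)
  if (lo > hi) stop("`lo` must not exceed `hi`.", call. = FALSE)
  k <- round((hi - lo) / step)
  cutoffs <- lo + (0:k) * step
  structure(cutoffs, scale = scale, class = c("cutoff_grid", "numeric"))
}

#' Dichotomize an exposure at a cutoff
#'
#' Classifies each value as exposed (1) when `w >= phi` and unexposed (0)
#' when `w < phi`: the boundary belongs to the exposed group, and the
#' unexposed group is the reference.
#'
#' @param w Numeric vector of exposure values.
#' @param phi Cutoff (raw scale).
#' @return Integer vector of 0/1.
#' @export
dichotomize <- function(w, phi) {
  as.integer(w >= phi)
}

#' Construct a five-category exposure scheme
#'
#' Four cutoffs `phi = center + sd * delta * (-1.5, -0.5, 0.5, 1.5)` define
#' five categories: three interior groups of equal width `delta * sd`
#' (categories 2, 3 and 4, with category 3 the reference, centered on the
#' cohort mean) and two unbounded extreme groups (1 and 5).
#'
#' @param delta Reference-group width in SD units (positive).
#' @param center Exposure mean (midpoint of the reference category).
#' @param sd Exposure standard deviation (positive).
#' @return An object of class `category_scheme`: a list with `delta`,
#'   `phi` (the four cutoffs), `center`, `sd` and `reference = 3`.
#' @examples
#' make_category_scheme(1, 0, 1)$phi # -1.5 -0.5 0.5 1.5
#' @export
make_category_scheme <- function(delta, center, sd) {
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be positive.", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive.", call. = FALSE)
  structure(
    list(
      delta = delta,
      phi = center + sd * delta * c(-1.5, -0.5, 0.5, 1.5),
      center = center,
      sd = sd,
      reference = 3L
    ),
    class = "category_scheme"
  )
}

#' Assign five-category exposure labels
#'
#' Categories are half-open on the right throughout, matching the referent
#' convention `phi_2 <= W < phi_3`: category 1 is `(-Inf, phi_1)`, category
#' k (2-4) is `[phi_{k-1}, phi_k)`, and category 5 is `[phi_4, Inf)`.
#'
#' @param w Numeric vector of exposure values.
#' @param scheme A [make_category_scheme()] object.
#' @return Integer vector in 1..5.
#' @export
assign_category <- function(w, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  findInterval(w, scheme$phi) + 1L
}
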