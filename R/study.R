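#' Define the full scenario grid of the simulation study
#'
#' The default grid crosses three exposure-response shapes with three
#' effect sizes and four measurement-error variances (sigma2 = 0 is the
#' no-measurement-error reference), 36 scenarios in total, each analyzed
#' over the 61-point dichotomization grid, the five-category widths
#' 0.5-1.5 SD, and ROC curves at the selected true-exposure cutoffs
#' -3..3 SD.
#'
#' @param shapes Character vector of model shapes.
#' @param beta1_values Effect sizes of the causal exposure.
#' @param sigma2_values Measurement-error variances for the causal exposure.
#' @param grid Dichotomization grid ([make_dichotomy_grid()]).
#' @param delta_values Reference-group widths for the five-category coding.
#' @param roc_phi_true True-exposure cutoffs (SD units) at which ROC curves
#'   are computed.
#' @param n Cohort size per scenario.
#' @param seed Master seed shared by all scenarios, so cohorts differing
#'   only in `sigma2` (or shape/effect size) share their covariate draws
#'   and comparisons are paired.
#' @param base_config Named list of further [scenario_config()] overrides
#'   applied to every scenario.
#' @return An object of class `study_grid`.
#' @export
study_grid <- function(shapes = c("linear", "threshold", "saturation"),
                       beta1_values = c(0.15, 0.25, 0.5),
                       sigma2_values = c(0, 0.0625, 0.25, 1),
                       grid = make_dichotomy_grid(),
                       delta_values = seq(0.5, 1.5, by = 0.1),
                       roc_phi_true = -3:3,
                       n = 1e6,
                       seed = 1L,
                       base_config = list()) {
  stopifnot(length(shapes) > 0, length(beta1_values) > 0,
            length(sigma2_values) > 0, length(grid) > 0)
  structure(
    list(
      shapes = shapes, beta1_values = beta1_values,
      sigma2_values = sigma2_values, grid = grid,
      delta_values = delta_values, roc_phi_true = roc_phi_true,
      n = as.integer(n), seed = as.integer(seed), base_config = base_config
    ),
    class = "study_grid"
  )
}

#' Enumerate the scenarios of a study grid
#'
#' @param study A [study_grid()].
#' @return A tibble with one row per scenario: `scenario` (identifier),
#'   `shape`, `beta1`, `sigma2`.
#' @export
scenario_plan <- function(study) {
  stopifnot(inherits(study, "study_grid"))
  plan <- expand.grid(
    sigma2 = study$sigma2_values,
    beta1 = study$beta1_values,
    shape = study$shapes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("shape", "beta1", "sigma2")]
  plan$scenario <- sprintf("%s_b%g_s%g", plan$shape, plan$beta1, plan$sigma2)
  tibble::as_tibble(plan[, c("scenario", "shape", "beta1", "sigma2")])
}

.scenario_config <- function(study, shape, beta1, sigma2) {
  args <- utils::modifyList(
    list(shape = shape, beta1 = beta1, sigma2_w1 = sigma2,
         n = study$n, seed = study$seed),
    study$base_config
  )
  do.call(scenario_config, args)
}

#' Run the full scenario grid
#'
#' Simulates each scenario once and computes all four analysis products:
#' odds-ratio curves over the cutoff grid (for the mismeasured exposure in
#' every scenario, plus one error-free reference curve per shape and effect
#' size), category odds-ratio tables, sensitivity/specificity curves by
#' stratum, and ROC curves at the selected true-exposure cutoffs. A failing
#' scenario is recorded in the manifest and the run continues. The entire
#' bundle is deterministic given the study's seed.
#'
#' @param study A [study_grid()].
#' @param quiet Suppress per-scenario progress messages.
#' @return An object of class `result_bundle`: a list of long-format
#'   tibbles `or_curves`, `category_or`, `sens_spec`, `roc`, plus a
#'   `manifest` list (study definition, package version, failures, runtime).
#' @export
run_grid <- function(study, quiet = FALSE) {
  stopifnot(inherits(study, "study_grid"))
  t0 <- Sys.time()
  plan <- scenario_plan(study)
  or_curves <- list()
  category_or <- list()
  sens <- list()
  roc <- list()
  failures <- list()

  for (i in seq_len(nrow(plan))) {
    sc <- plan[i, ]
    if (!quiet) message("scenario ", sc$scenario)
    res <- tryCatch({
      config <- .scenario_config(study, sc$shape, sc$beta1, sc$sigma2)
      cohort <- build_cohort(config)

      oc <- build_or_curve(cohort, study$grid, "observed")
      oc <- tibble::add_column(oc,
        scenario = sc$scenario, shape = sc$shape, beta1 = sc$beta1,
        sigma2 = sc$sigma2, exposure_source = "observed", .before = 1
      )
      # one error-free reference curve per (shape, beta1), computed on the
      # sigma2 = 0 cohort and tagged exposure_source = "true"
      if (sc$sigma2 == min(study$sigma2_values)) {
        tc <- build_or_curve(cohort, study$grid, "true")
        tc <- tibble::add_column(tc,
          scenario = sprintf("%s_b%g_true", sc$shape, sc$beta1),
          shape = sc$shape, beta1 = sc$beta1, sigma2 = NA_real_,
          exposure_source = "true", .before = 1
        )
        oc <- dplyr::bind_rows(oc, tc)
      }

      ct <- build_category_table(cohort, study$delta_values, "observed")
      ct <- tibble::add_column(ct,
        scenario = sc$scenario, shape = sc$shape, beta1 = sc$beta1,
        sigma2 = sc$sigma2, .before = 1
      )

      ss <- sens_spec_curve(cohort, study$grid)
      ss <- tibble::add_column(ss,
        scenario = sc$scenario, shape = sc$shape, beta1 = sc$beta1,
        sigma2 = sc$sigma2, .before = 1
      )

      rc <- dplyr::bind_rows(lapply(study$roc_phi_true, function(k) {
        phi_true <- mean(cohort$w1) + k * stats::sd(cohort$w1)
        r <- roc_points(cohort, phi_true)
        if (nrow(r$points) == 0) return(NULL)
        tibble::tibble(
          scenario = sc$scenario, shape = sc$shape, beta1 = sc$beta1,
          sigma2 = sc$sigma2, phi_true_sd = k, phi_true = phi_true,
          threshold = r$points$threshold, fpr = r$points$fpr,
          tpr = r$points$tpr, auc = r$auc
        )
      }))
      list(oc = oc, ct = ct, ss = ss, rc = rc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sc$scenario]] <- conditionMessage(res)
    } else {
      or_curves[[i]] <- res$oc
      category_or[[i]] <- res$ct
      sens[[i]] <- res$ss
      roc[[i]] <- res$rc
    }
  }

  manifest <- list(
    study = list(
      shapes = study$shapes, beta1_values = study$beta1_values,
      sigma2_values = study$sigma2_values,
      grid = as.numeric(study$grid), grid_scale = attr(study$grid, "scale"),
      delta_values = study$delta_values, roc_phi_true = study$roc_phi_true,
      n = study$n, seed = study$seed, base_config = study$base_config
    ),
    n_scenarios = nrow(plan),
    failures = failures,
    package_version = as.character(utils::packageVersion("orcurve")),
    r_version = R.version.string,
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(
    list(
      or_curves = dplyr::bind_rows(or_curves),
      category_or = dplyr::bind_rows(category_or),
      sens_spec = dplyr::bind_rows(sens),
      roc = dplyr::bind_rows(roc),
      manifest = manifest
    ),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  cat(sprintf("  scenarios: %d (failures: %d)\n",
              x$manifest$n_scenarios, length(x$manifest$failures)))
  cat(sprintf("  or_curves: %d rows   category_or: %d rows\n",
              nrow(x$or_curves), nrow(x$category_or)))
  cat(sprintf("  sens_spec: %d rows   roc: %d rows\n",
              nrow(x$sens_spec), nrow(x$roc)))
  invisible(x)
}

#' Persist a result bundle as long-format CSV tables plus a JSON manifest
#'
#' Writes `or_curves.csv`, `category_or.csv`, `sens_spec.csv`, `roc.csv`
#' and `manifest.json` into `dir`. Reruns with the same study definition
#' regenerate byte-identical CSV files.
#'
#' @param bundle A [run_grid()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$or_curves, file.path(dir, "or_curves.csv"))
  readr::write_csv(bundle$category_or, file.path(dir, "category_or.csv"))
  readr::write_csv(bundle$sens_spec, file.path(dir, "sens_spec.csv"))
  readr::write_csv(bundle$roc, file.path(dir, "roc.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.save_plot <- function(p, dir, name, formats, width = 9, height = 6) {
  paths <- character(0)
  for (fmt in formats) {
    f <- file.path(dir, paste0(name, ".", fmt))
    ok <- tryCatch({
      ggplot2::ggsave(f, p, width = width, height = height, dpi = 150)
      TRUE
    }, error = function(e) {
      warning("Could not write ", f, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) paths <- c(paths, f)
  }
  paths
}

#' Render the study's figure types from a result bundle
#'
#' Produces the four figure families: odds ratio vs cutoff (one line per
#' error variance, plus the error-free reference), category odds ratios vs
#' reference-group width, sensitivity/specificity vs cutoff by stratum,
#' and ROC panels. Missing (non-estimable) points are rendered as gaps.
#'
#' @param bundle A [run_grid()] result.
#' @param dir Output directory.
#' @param formats Image formats understood by [ggplot2::ggsave()].
#' @return Character vector of files written (empty, with a warning, for an
#'   empty bundle).
#' @export
render_figures <- function(bundle, dir, formats = c("png", "svg")) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (nrow(bundle$or_curves) == 0) {
    warning("Empty result bundle: no figures rendered.")
    return(character(0))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  oc <- bundle$or_curves
  oc$error <- ifelse(oc$exposure_source == "true", "none (true exposure)",
                     paste0("sigma2 = ", oc$sigma2))
  p1 <- ggplot2::ggplot(oc, ggplot2::aes(x = phi, y = or, colour = error)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_grid(beta1 ~ shape, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "cutoff (SD from mean)", y = "odds ratio",
                  colour = "measurement error",
                  title = "Odds ratio vs dichotomization cutoff") +
    ggplot2::theme_minimal()
  files <- c(files, .save_plot(p1, dir, "or_curves", formats))

  if (nrow(bundle$category_or) > 0) {
    ct <- bundle$category_or
    ct$category <- factor(ct$category)
    p2 <- ggplot2::ggplot(ct, ggplot2::aes(x = delta, y = or, colour = category)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
      ggplot2::facet_grid(beta1 + sigma2 ~ shape, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "reference-group width delta (SD)",
                    y = "odds ratio vs reference category",
                    title = "Five-category odds ratios vs reference width") +
      ggplot2::theme_minimal()
    files <- c(files, .save_plot(p2, dir, "category_or", formats, height = 8))
  }

  if (nrow(bundle$sens_spec) > 0) {
    ss <- tidyr::pivot_longer(bundle$sens_spec, c("sensitivity", "specificity"),
                              names_to = "measure", values_to = "value")
    p3 <- ggplot2::ggplot(ss, ggplot2::aes(x = phi, y = value,
                                           colour = group, linetype = measure)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::facet_grid(beta1 + sigma2 ~ shape, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "cutoff (SD from mean)", y = "proportion",
                    title = "Exposure-classification sensitivity and specificity") +
      ggplot2::theme_minimal()
    files <- c(files, .save_plot(p3, dir, "sens_spec", formats, height = 8))
  }

  if (nrow(bundle$roc) > 0) {
    rc <- bundle$roc
    rc$cutoff <- factor(rc$phi_true_sd)
    p4 <- ggplot2::ggplot(rc, ggplot2::aes(x = fpr, y = tpr, colour = cutoff)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey50") +
      ggplot2::facet_grid(beta1 + sigma2 ~ shape, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                    colour = "true cutoff (SD)",
                    title = "ROC of the mismeasured exposure against true exposure status") +
      ggplot2::theme_minimal()
    files <- c(files, .save_plot(p4, dir, "roc", formats, height = 8))
  }
  files
}
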