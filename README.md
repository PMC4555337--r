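# orcurve

Cutoffs chosen to categorize a continuous exposure can have profound effects
on epidemiological study results. When the exposure is also measured with
classical error, categorizing it does something worse than lose information:
it turns *non-differential* measurement error into *differential*
misclassification of the resulting binary exposure, because subjects near the
cutoff are misclassified at rates that depend on their (exposure-driven)
outcome status. `orcurve` is a simulation toolkit for studying both effects:
it generates a large synthetic birth cohort with a mismeasured exposure,
sweeps the dichotomization cutoff over a grid, fits an adjusted logistic
model at every cutoff, and quantifies the misclassification the cutoff
induces — the tools an epidemiologist needs to see how the *shape* of the
odds-ratio-versus-cutoff curve ("OR curve") reflects, or hides, the true
exposure-response relationship.

## The model

A cohort of `n` children is simulated with:

- **Exposures** `X1, X2 ~ N(0, 1)`, Pearson correlation ρ = 0.7; only `X1`
  is causal. Observed versions carry classical error:
  `W1 = X1 + ε1`, `ε1 ~ N(0, σ²)` with σ² ∈ {0, 0.0625, 0.25, 1}, and
  `W2 = X2 + ε2`, `ε2 ~ N(0, 0.25)`.
- **Sex** `Z ~ Bernoulli(0.5)` (1 = male).
- **Gestational age** `X_ga = 43 − γ` weeks, `γ ~ χ²(3)`, with a 1-week
  reduction for 5% of males; the observed value is rounded to whole weeks
  and only 23–43 weeks (inclusive) are retained in the cohort.
- **Latent outcome** under three shapes, with `ε_y ~ N(0, 1)` and inflection
  point `μ_x1 − σ_x1` (≈ −1):

  | shape | below inflection | at/above inflection |
  |---|---|---|
  | linear | `β1·X1` | `β1·X1` |
  | threshold | no effect | `1.5·β1·X1` |
  | saturation | `1.5·β1·X1` | `0.5·β1·X1` |

  plus `β2·X2 + β3·Z + β4·X_ga + ε_y` in every branch
  (β2 = 0, β3 = 1, β4 = 0.1), with β1 ∈ {0.15, 0.25, 0.5}.
- **Case status**: the latent outcome is mapped monotonically to an integer
  severity score on 0–18 (an AOSI-like instrument); scores ≥ 7 define cases.

For each cutoff φ on a 61-point grid (mean ± 3 SD in steps of 0.1 SD) the
exposure is dichotomized (`W1c = 1` iff `W1 ≥ φ`) and

```
logit P(case = 1) = c0 + c1·W1c + c2·W2c + c3·Z + c4·W_gac
```

is fitted by maximum likelihood; `exp(c1)` is the odds ratio plotted against
φ. A five-category analysis varies the width δ of a mean-centered reference
category from 0.5 to 1.5 SD. For each cutoff, the sensitivity and specificity
of the dichotomized `W1` against the dichotomized error-free `X1` are
computed separately for cases and controls, along with ROC curves.

## Worked example

```r
library(orcurve)

cfg <- scenario_config(shape = "linear", beta1 = 0.5, sigma2_w1 = 0.25,
                       n = 2e5, seed = 2024)
cohort <- build_cohort(cfg)
sum(cohort$case)
#> [1] 34316

build_or_curve(cohort, make_dichotomy_grid(-2, 2, 1))
#> # A tibble: 5 × 8
#>     phi  phi_raw    or ci_lo ci_hi n_exposed_cases converged separation
#>   <dbl>    <dbl> <dbl> <dbl> <dbl>           <int> <lgl>     <lgl>
#> 1    -2 -2.24     8.37  6.89 10.2            34211 TRUE      FALSE
#> 2    -1 -1.12     3.71  3.52  3.90           32505 TRUE      FALSE
#> 3     0 -0.00409  2.86  2.78  2.94           24383 TRUE      FALSE
#> 4     1  1.11     2.97  2.88  3.07           10655 TRUE      FALSE
#> 5     2  2.23     3.61  3.38  3.87            2050 TRUE      FALSE
```

The odds ratio from the *same* cohort and the *same* linear association
ranges from 2.9 to 8.4 depending only on where the cutoff is placed — the
U-shape characteristic of a truly linear exposure-response. Refitting with
the error-free exposure (`exposure_source = "true"`) gives 3.40 at the
central cutoff versus 2.86 above: classical error attenuates the OR.

The misclassification created by dichotomizing the noisy exposure is
differential, as theory predicts — sensitivity is higher among cases and
specificity higher among controls:

```r
sens_spec(cohort, phi = 1, "cases")[, 3:4]
#>   sensitivity specificity
#> 1       0.810       0.876
sens_spec(cohort, phi = 1, "controls")[, 3:4]
#>   sensitivity specificity
#> 1       0.772       0.935
```

The full 36-scenario study (3 shapes × 3 effect sizes × 4 error variances)
runs with:

```r
bundle <- run_grid(study_grid(n = 1e5, seed = 1))
write_result_bundle(bundle, "results")
render_figures(bundle, "results")
```

or from the shell via `Rscript inst/scripts/run-study.R run --reduced`.
Scenarios sharing a seed share their covariate draws, so comparisons across
error variances are paired.

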