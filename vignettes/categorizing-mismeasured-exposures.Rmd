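---
title: "Categorizing mismeasured exposures: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing mismeasured exposures: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcurve)
```

## What the package simulates, and why

When a continuous exposure is dichotomized at a cutoff $\varphi$, the odds
ratio (OR) comparing "exposed" ($W \ge \varphi$) to "unexposed" depends on
$\varphi$ even when the underlying per-unit association is constant. When the
exposure is additionally measured with classical error, the binary variable
obtained by cutting the *noisy* measurement is a misclassified version of the
binary variable one intended to study, and — crucially — the misclassification
is *differential* whenever the exposure truly affects the outcome: cases are
drawn preferentially from the upper tail of the true exposure distribution,
where a subject near the cutoff is more likely to be pushed across it in one
direction than the other.

`orcurve` makes both phenomena visible by simulation. It generates a
population-scale cohort (the default is one million subjects, large enough
that sampling error and small strata are not an issue), sweeps the cutoff
over a grid, and measures what the analyst would see: the OR curve, the
category-specific ORs of a five-group coding, and the cutoff-specific
sensitivity/specificity of the exposure classifier by case status.

## The data-generating process

Per subject the generator draws:

* $X_1, X_2$ jointly Gaussian with standard margins and correlation
  $\rho = 0.7$; only $X_1$ is causal ($\beta_2 = 0$), so $X_2$ plays the role
  of a correlated but inert co-exposure and there is no confounding.
* $Z \sim \text{Bernoulli}(0.5)$ (1 = male).
* Gestational age $X_{ga} = 43 - \gamma$ weeks with
  $\gamma \sim \chi^2(3)$; 5% of males get a further one-week reduction,
  reflecting shorter gestation among boys. The observed value
  $W_{ga}$ adds $N(0, \sigma^2_{ga})$ error, is rounded to whole weeks, and
  subjects outside 23–43 weeks are excluded (live-birth inclusion window).
* Observed exposures $W_j = X_j + \varepsilon_j$ with
  $\varepsilon_1 \sim N(0, \sigma^2)$, $\sigma^2 \in \{0, 0.0625, 0.25, 1\}$
  spanning no error to error as large as the true exposure variance, and
  $\varepsilon_2 \sim N(0, 0.25)$.
* A latent outcome $Y$ under one of three shapes (linear, threshold,
  saturation; see the README for the branch formulas), with the inflection
  point of the piecewise shapes at $\bar{x}_1 - s_{x_1}$ computed from the
  realized cohort rather than hard-coded at $-1$.
* An integer severity score on 0–18 via a monotone transform of $Y$
  (below); scores $\ge 7$ define cases.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `beta1` | 0.5 | latent-outcome units per SD of $X_1$ | true effect; 0.15/0.25/0.5 = weak/moderate/strong |
| `sigma2_w1` | 0.25 | variance | exposure measurement error; 0 = none |
| `rho` | 0.7 | — | exposure correlation |
| `beta3`, `beta4` | 1, 0.1 | latent units | sex and gestational-age effects (not confounders) |
| `sigma2_ga` | $(1/7)^2$ | weeks$^2$ | continuous gestational-age error (about one day) |
| `aosi_mu_log`, `aosi_sigma_log` | 1.3, 0.6 | log-score units | location/scale of the severity transform |
| `case_cutoff` | 7 | score points | case definition |
| `n` | $10^6$ | subjects | cohort size after inclusion |

`beta4 = +0.1` is kept exactly as specified for the study conditions even
though a positive gestational-age coefficient is counterintuitive for this
outcome; it is config-overridable.

## Design choices where the design was open

**The severity transform.** The study conditions call for a score whose
distribution resembles an empirical autism-screening instrument, without
giving its parameters. We use the monotone map
$\text{score} = \text{clamp}(\text{round}(\exp(\mu + \sigma_{\log}
\cdot \text{standardize}(y))), 0, 18)$ with defaults $\mu = 1.3$,
$\sigma_{\log} = 0.6$. This is a *stand-in*, not a reproduction of any real
instrument's data: under the defaults the case prevalence
$P(\text{score} \ge 7)$ is about 0.17 (the lognormal tail above
$(\log 6.5 - 1.3)/0.6 \approx 0.95$ standard deviations), a plausible value
for an enriched-risk cohort. Because the map is monotone, every qualitative
conclusion about OR-curve shapes is invariant to its parameters; only the
prevalence and hence absolute OR levels move. Consequently printed
case-count figures are not reproducible quantities and are not targeted.

**Rounding.** The rounding operator rounds to the nearest integer with ties
away from zero; a `floor` mode ("completed weeks") is provided. The choice
is visible only on the half-integer grid and is pinned down by an
enumerated-oracle test.

**Truncation semantics.** For gestational age, "truncation" is read as
*exclusion*: out-of-range subjects are dropped and the generator redraws
until exactly `n` subjects remain, preserving the stated cohort size. For
the severity score, exclusion would silently shrink the cohort, so
out-of-range scores are clamped to the bounds instead. This asymmetry is
deliberate.

**Gestational-age error variance.** The continuous error variance defaults
to $(1/7)^2$ — a one-day reporting error — as the plausible reading among
the candidates ($17^2$ would dominate the signal entirely and interact
pathologically with the inclusion window; $1.72$ has no interpretation in
weeks). It is configurable, and a pathological value (error SD comparable to
the inclusion window itself) makes the builder abort with a retention
diagnostic rather than loop.

**Cutoff scale.** "Mean ± 3 SD" and a raw $-3$ to $3$ grid coincide only
when $\mathrm{SD}(W_1) = 1$, i.e. without measurement error. The default
anchors cutoffs at the empirical mean and SD of the exposure column being
cut, which honors both readings when the error is small and yields exactly
61 cutoffs; a raw-scale mode is provided.

**Random streams.** One master seed spawns named substreams (covariates,
sex, shift, gestational age, each error, outcome noise), so toggling one
variance never perturbs another stream's draws. Cohorts differing only in
`sigma2_w1` share their covariate draws and their standard-normal error
draws (scaled by $\sigma$), making comparisons across error variances
paired — a variance-reduction choice that sharpens the monotone-attenuation
checks. The error-free reference model is computed once per shape and effect
size and reused across error variances.

**Estimation.** All predictors in the logistic model are categorical, so the
likelihood depends on the data only through covariate-pattern counts; fits
are computed on at most 32 (dichotomous) or 80 (five-category) weighted rows
via `stats::glm`, which is what keeps a 61-cutoff sweep over a million-row
cohort at a few seconds. The equivalence with the row-level fit is asserted
to six decimals in the tests. Wald 95% intervals are attached as plumbing;
the study's substantive output is the OR curve itself, and no
multiple-testing adjustment is applied anywhere — the curve is a descriptive
object, not a family of hypothesis tests.

**Degenerate fits.** Extreme cutoffs produce zero cells. A zero
exposure-by-outcome margin means the corresponding log-odds contrast
diverges: the fit is flagged (`separation`), the OR is reported as missing,
and the curve continues — gaps and instability at the extremes are part of
the phenomenon under study, not an error to suppress. Likewise 0/0
sensitivity or specificity ratios are reported as missing rather than 0
or 1.

**ROC construction.** One curve per "true" cutoff: the truth is fixed by
dichotomizing the error-free exposure at that cutoff, and the noisy
exposure is swept as a continuous classifier over the threshold grid; the
trapezoidal AUC is attached. This is the only construction consistent with
one curve per selected cutoff.

## What the generator does and does not emulate

The synthetic cohort reproduces the *structure* of a birth-cohort study —
correlated exposures, demographic covariates with realistic marginals, an
inclusion window, an instrument-bounded integer outcome — under exactly
known truth, which is what makes bias measurable. It deliberately omits:
confounding (all covariate effects are independent by construction),
finite-sample designs (analyses use the whole population, so sampling error
is absent), selection processes other than the gestational-age window,
non-Gaussian or differential measurement error, and any attempt to match a
real instrument's score distribution. Passing tests therefore demonstrate
properties of categorization under classical error — not that any specific
real-world dataset would show effects of the same magnitude.

## Problem sizes and numerical tolerances

Unit and property tests run at $n$ between $10^3$ and $2 \times 10^5$, sized
so each stochastic assertion sits at least four Monte-Carlo standard errors
from its boundary under the fixed test seeds. The population-scale checks of
the substantive claims (attenuation monotonicity with non-overlapping CIs,
the U-shape, inflection-point overestimation, differential
misclassification) run at the full $n = 10^6$. Independent oracles back the
non-trivial expectations: exhaustive enumeration for rounding and category
assignment, the 2×2 cross-product ratio and a row-level `glm` for the
collapsed logistic fit, and one-dimensional Gaussian quadrature
(`stats::integrate`) over the joint law of $(X_1, W_1)$ for sensitivity,
specificity and AUC. Equality of collapsed and row-level fits is required to
$10^{-6}$; quadrature comparisons use three binomial standard errors.

## Known limitations

* The severity transform standardizes $y$ within the cohort, so the
  mapping — and with it the realized prevalence — depends mildly on the
  scenario; this mirrors instrument calibration on the study population but
  means scores are not comparable across scenarios subject-by-subject.
* The piecewise threshold/saturation formulas imply a discontinuity of the
  latent mean at the inflection point; they are implemented exactly as
  stated rather than continuity-corrected.
* Five-category fits at extreme reference widths can empty the outer
  categories in small cohorts; affected contrasts are reported missing.
* The package quantifies bias; it does not correct for it. Measurement-error
  correction and changepoint estimation are out of scope.
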