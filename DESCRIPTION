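Package: orcurve
Title: Odds-Ratio Curves for Categorized Mismeasured Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how the choice of cutoff(s) used to
    categorize a continuous exposure measured with classical error distorts odds
    ratios and induces differential exposure misclassification. Generates a
    reproducible synthetic birth cohort with correlated exposures, sex and
    gestational age, latent outcomes under linear, threshold and saturation
    exposure-response shapes, and an integer severity score defining case
    status; dichotomizes the observed exposure over a grid of cutoffs and into
    five-category schemes; fits adjusted logistic models per cutoff to build
    odds-ratio curves; and computes cutoff-specific sensitivity, specificity
    and ROC curves stratified by case status.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
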