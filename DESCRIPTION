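Package: emraking
Title: Generalized Raking Estimation of Pregnancy Incidence from
    Validation-Sampled EMR Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating adjusted incidence rate ratios of pregnancy
    under concomitant contraceptive and antiretroviral therapy use from
    error-prone electronic medical record (EMR) data, using multi-phase
    validation sampling. Converts visit-level records into observation
    periods with exposure-coding hierarchies, conception-date backdating and
    38-week pregnancy censoring; draws stratified phase-2 (chart review) and
    priority phase-3 (interview) validation samples; reconciles records
    across phases; and fits Poisson rate models with cluster-robust sandwich
    variance, inverse-probability weights calibrated by generalized raking
    against influence functions from the full-cohort fit, and multiple
    imputation by chained equations. A synthetic-cohort generator with known
    true rate ratios and configurable misclassification supports end-to-end
    simulation studies of bias, coverage and efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
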