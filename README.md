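# emraking

Generalized-raking estimation of pregnancy incidence under concomitant
contraceptive and antiretroviral therapy (ART) use from error-prone
electronic medical record (EMR) cohorts, corrected by multi-phase
validation sampling.

The package implements the full pipeline:

1. **Cohort coding** — visit-level records to observation periods:
   contraceptive hierarchy (MEC > implant > DMPA > OCP > LEC), three-drug
   ART categorization anchored on efavirenz / nevirapine / protease
   inhibitors, conception backdating (LMP > gestational age > EDD), and
   38-week pregnancy censoring.
2. **Synthetic data** — an EMR-like generator with known true rate
   ratios, per-phase misclassification, and MCAR covariate missingness.
3. **Validation sampling** — stratified phase-2 chart-review sampling
   over 32 exposure-by-pregnancy strata, priority phase-3 interview
   sampling, logistic `p2` models, and interview > chart > EMR record
   reconciliation.
4. **Estimation** — Poisson rate models with cluster-robust sandwich
   variance and per-woman influence functions, inverse-probability
   weights calibrated by generalized raking, within-stratum aIRR
   contrasts, and chained-equation multiple imputation with Rubin
   pooling.
5. **Simulation study** — end-to-end Monte-Carlo replicates reporting
   bias, coverage and relative efficiency, plus a thin CLI.

See `vignettes/methods.Rmd` for the statistical details and design
decisions.

## Worked example

```r
library(emraking)

# a synthetic study whose true implant EFV-vs-NVP rate ratio is 3.2
cfg <- truth_config(n_women = 2000, seed = 42)
design <- sampling_design(phase3_budget = 100L)
study <- generate_cohort(cfg, phases = c("emr", "chart"))

# phase 1: code the EMR and fit the naive interaction model
emr <- code_cohort(study$emr_visits, study_end = cfg$study_end,
                   lookahead_days = cfg$lookahead_days)
periods <- prepare_periods(emr)
naive <- fit_poisson_robust(periods, pregnancy ~ contraceptive * art)
irr_contrasts(naive, default_contrasts()["implant_efv_vs_nvp"])
#>                 stratum        contrast   log_irr se_log_irr     aIRR   ci_low ci_high
#> 1 contraceptive=IMPLANT art: EFV vs NVP 0.9167824  0.2929546 2.501229 1.408608 4.44137

# phase 2: stratified chart validation of ~7.6% of women
assignments <- sample_phase2(assign_strata(periods), design, seed = 43)
validated <- validated_cohort(
  study$emr_visits, study$chart_visits, NULL,
  women = assignments$woman_id[assignments$sampled_phase2],
  study_end = cfg$study_end, lookahead_days = cfg$lookahead_days)

# raking-calibrated corrected fit (weights calibrated to the influence
# function of the target contrast)
proj <- contrast_matrix(naive, default_contrasts()["implant_efv_vs_nvp"],
                        data = periods)
corrected <- weighted_corrected_fit(
  prepare_periods(validated), assignments, naive,
  pregnancy ~ contraceptive * art, phase = "chart", aux_projection = proj)
irr_contrasts(corrected, default_contrasts()["implant_efv_vs_nvp"])
#>                 stratum        contrast  log_irr se_log_irr     aIRR   ci_low  ci_high
#> 1 contraceptive=IMPLANT art: EFV vs NVP 1.745499  0.3811937 5.728762 2.713864 12.09298

log(3.2)  # the generating truth
#> [1] 1.163151
```

The naive EMR estimate (aIRR 2.50) is attenuated toward 1 because
implants are under-recorded in the EMR; the corrected estimate moves
back up and its CI covers the truth (3.2). Any single replicate is
noisy (the corrected SE here is 0.38 on the log scale); the systematic
comparison is the Monte-Carlo study below.

## Monte-Carlo study

```r
st <- run_study(cfg, design,
                estimators = c("naive_emr", "ipw_chart", "raking_chart"),
                n_replicates = 200, base_seed = 2000)
print(st)
```

At the defaults (200 replicates, n = 2000) the naive estimator is biased
by about -0.58 on the log scale with ~49% CI coverage, while plain IPW
and the raking estimator are unbiased with ~95% coverage, raking at or
below IPW's Monte-Carlo variance.

## Command line

```sh
inst/cli/emraking generate --config truth.yaml --seed 1 --out study/
inst/cli/emraking code --visits study/emr_visits.csv --out periods.csv
inst/cli/emraking sample --periods periods.csv --config design.yaml --out assignments.csv
inst/cli/emraking simulate --config study.yaml --seed 1 --out results/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 2000 --out acceptance.json
```

runs the pipeline end-to-end against the installed package (including
the 200-replicate study) and writes the headline quantities as JSON.
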