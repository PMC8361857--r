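# Shared fixtures and memoized heavy runs for the test suite.

D0 <- as.Date("2012-01-01")

# build a visit table from day offsets relative to D0
mk_visits <- function(woman_id, days, contraceptive = "none", art = "",
                      preg_reported = FALSE, lmp_day = NA_real_,
                      gest_age_weeks = NA_real_, edd_day = NA_real_,
                      outcome_day = NA_real_, ...) {
  n <- length(days)
  v <- data.frame(
    woman_id = rep_len(woman_id, n),
    visit_date = D0 + days,
    contraceptive_codes = rep_len(contraceptive, n),
    art_drugs = rep_len(art, n),
    preg_reported = rep_len(preg_reported, n),
    lmp_date = D0 + rep_len(lmp_day, n),
    gest_age_weeks = rep_len(gest_age_weeks, n),
    edd_date = D0 + rep_len(edd_day, n),
    outcome_date = D0 + rep_len(outcome_day, n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) v[[nm]] <- rep_len(extra[[nm]], n)
  v
}

# a generator config with *no* recording errors anywhere
identity_config <- identity_truth_config

# memoized expensive runs, shared across test files within one session
.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache, inherits = FALSE)
}

# the main Monte-Carlo study backing acceptance criteria 4-6
main_study <- function() {
  memo("main_study", {
    suppressWarnings(suppressMessages(run_study(
      truth_config(n_women = 2000),
      sampling_design(phase3_budget = 100L),
      estimators = c("naive_emr", "ipw_chart", "raking_chart"),
      n_replicates = 200L, base_seed = 2000L
    )))
  })
}

# the multiple-imputation study backing acceptance criterion 8: error-free
# recording, CD4 masked MCAR at 25.7%, pooled covariate-adjusted fits
mi_study <- function(n_replicates = 200L) {
  memo("mi_study", {
    suppressWarnings(suppressMessages(run_study(
      identity_config(n_women = 2000, missingness = c(cd4 = 0.257)),
      sampling_design(),
      formula = pregnancy ~ contraceptive * art + cd4 + sqrt(cd4),
      estimators = "naive_emr", n_replicates = n_replicates,
      base_seed = 4000L, m = 5L
    )))
  })
}
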