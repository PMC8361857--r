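## End-to-end replicate experiments: generate -> code -> sample ->
## reconcile -> estimate, and Monte-Carlo aggregation.

ESTIMATORS <- c("naive_emr", "unweighted_chart", "ipw_chart", "raking_chart",
                "unweighted_interview", "ipw_interview", "raking_interview")

#' True log IRR implied by a config for a contrast specification
#'
#' @param config A [truth_config()].
#' @param ct One contrast specification (see [default_contrasts()]).
#' @return The true within-stratum log rate ratio.
#' @export
truth_contrast <- function(config, ct) {
  r <- config$rates
  if (ct$stratum_var == "contraceptive") {
    log(r[ct$stratum, ct$a]) - log(r[ct$stratum, ct$b])
  } else {
    log(r[ct$a, ct$stratum]) - log(r[ct$b, ct$stratum])
  }
}

## fit (possibly under multiple imputation) and extract contrasts
.fit_and_contrast <- function(periods, formula, contrasts, weights = NULL,
                              mi = FALSE, m = 10L, seed = 1L, fitter = NULL) {
  if (!mi) {
    fit <- if (is.null(fitter)) {
      fit_poisson_robust(periods, formula = formula, weights = weights)
    } else {
      fitter(periods)
    }
    return(list(fit = fit, irr = irr_contrasts(fit, contrasts, data = periods)))
  }
  imps <- impute_chained(periods, m = m, seed = seed)
  fits <- lapply(imps, function(dat) {
    if (is.null(fitter)) {
      fit_poisson_robust(dat, formula = formula, weights = weights)
    } else {
      fitter(dat)
    }
  })
  fit <- pool_rubin(fits)
  list(fit = fit, irr = irr_contrasts(fit, contrasts, data = imps[[1L]]))
}

#' Run one end-to-end simulation replicate
#'
#' Generates a synthetic study, codes the EMR visits into periods, fits the
#' naive Poisson model (with chained-equation multiple imputation if model
#' covariates are missing), draws the phase-2 and phase-3 validation
#' samples, reconciles the sampled women's records, and computes the
#' requested estimators of the target contrasts: naive EMR, and
#' unweighted / plain-IPW / raking-calibrated fits on chart-validated and
#' interview-validated data. Deterministic given `seed`.
#'
#' @param truth A [truth_config()] (its `seed` element is replaced by
#'   `seed`).
#' @param design A [sampling_design()].
#' @param formula Analysis model formula.
#' @param contrasts Contrast list (see [default_contrasts()]); only
#'   contrasts named here are reported.
#' @param estimators Subset of the available estimator labels.
#' @param seed Integer replicate seed.
#' @param m Number of imputations when model covariates are missing.
#' @param variance Variance estimator passed to [weighted_corrected_fit()]
#'   (default `"fixed_weight"`: calibrated weights treated as fixed in the
#'   cluster-robust sandwich). Raking calibrates to the influence functions
#'   of the target contrasts (see the `aux_projection` argument of
#'   [weighted_corrected_fit()]).
#' @return A data frame, one row per estimator x contrast, with the log
#'   IRR, its SE, the 95% CI, and failure bookkeeping (class
#'   `replicate_result`); failed estimator paths are recorded with the
#'   stage error message, never silently dropped.
#' @export
run_replicate <- function(truth, design, formula = default_formula(),
                          contrasts = default_contrasts()["implant_efv_vs_nvp"],
                          estimators = ESTIMATORS,
                          seed = 1L, m = 10L,
                          variance = "fixed_weight") {
  estimators <- match.arg(estimators, ESTIMATORS, several.ok = TRUE)
  config <- truth
  config$seed <- as.integer(seed)
  need_chart <- any(grepl("chart", estimators))
  need_int <- any(grepl("interview", estimators))
  phases <- c("emr", if (need_chart || need_int) "chart", if (need_int) "interview")
  study <- generate_cohort(config, phases = phases)
  emr <- code_cohort(study$emr_visits, study_end = config$study_end,
                     lookahead_days = config$lookahead_days)
  periods <- prepare_periods(emr)
  model_vars <- setdiff(all.vars(formula), c("pregnancy"))
  mi <- anyNA(periods[, intersect(model_vars, names(periods)), drop = FALSE])

  rows <- list()
  note <- function(estimator, irr, error = NA_character_) {
    if (is.null(irr)) {
      irr <- data.frame(stratum = NA, contrast = names(contrasts),
                        log_irr = NA_real_, se_log_irr = NA_real_,
                        aIRR = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    } else {
      irr$contrast <- names(contrasts)
    }
    irr$estimator <- estimator
    irr$error <- error
    rows[[length(rows) + 1L]] <<- irr
  }
  try_path <- function(estimator, expr) {
    if (!estimator %in% estimators) return(invisible(NULL))
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(res)) note(estimator, NULL, error = res) else note(estimator, res$irr)
    invisible(NULL)
  }

  ## --- naive (phase-1) fit; always needed when raking is requested ------
  naive <- tryCatch(
    .fit_and_contrast(periods, formula, contrasts, mi = mi, m = m, seed = seed + 11L),
    error = function(e) conditionMessage(e))
  if (is.character(naive)) {
    if ("naive_emr" %in% estimators) note("naive_emr", NULL, error = naive)
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    class(out) <- c("replicate_result", class(out))
    return(out)
  }
  if ("naive_emr" %in% estimators) note("naive_emr", naive$irr)

  if (need_chart || need_int) {
    strata <- assign_strata(periods)
    assignments <- sample_phase2(strata, design, seed = seed + 1L)
    assignments <- sample_phase3(assignments, design,
                                 reachable = study$women, seed = seed + 2L)
    ph2_women <- assignments$woman_id[assignments$sampled_phase2]
    ph3_women <- assignments$woman_id[assignments$sampled_phase3]

    ## calibrate to the influence functions of the target contrasts only:
    ## one constraint per coefficient over-fits small validation samples
    proj <- tryCatch(contrast_matrix(naive$fit, contrasts, data = periods),
                     error = function(e) NULL)
    corrected <- function(vc, phase, calibrate) {
      vp <- prepare_periods(vc)
      fitter <- function(dat) {
        weighted_corrected_fit(dat, assignments, naive$fit, formula = formula,
                               phase = phase, calibrate = calibrate,
                               variance = variance, aux_projection = proj)
      }
      .fit_and_contrast(vp, formula, contrasts, mi = mi, m = m,
                        seed = seed + 13L, fitter = fitter)
    }
    if (need_chart) {
      vc_chart <- validated_cohort(
        study$emr_visits, study$chart_visits, NULL, women = ph2_women,
        study_end = config$study_end, lookahead_days = config$lookahead_days)
      try_path("unweighted_chart", {
        .fit_and_contrast(prepare_periods(vc_chart), formula, contrasts,
                          mi = mi, m = m, seed = seed + 12L)
      })
      try_path("ipw_chart", corrected(vc_chart, "chart", calibrate = FALSE))
      try_path("raking_chart", corrected(vc_chart, "chart", calibrate = TRUE))
    }
    if (need_int && length(ph3_women)) {
      vc_int <- validated_cohort(
        study$emr_visits,
        study$chart_visits[study$chart_visits$woman_id %in% ph3_women, , drop = FALSE],
        study$interview_visits[study$interview_visits$woman_id %in% ph3_women, , drop = FALSE],
        women = ph3_women,
        study_end = config$study_end, lookahead_days = config$lookahead_days)
      try_path("unweighted_interview", {
        .fit_and_contrast(prepare_periods(vc_int), formula, contrasts,
                          mi = mi, m = m, seed = seed + 12L)
      })
      try_path("ipw_interview", corrected(vc_int, "interview", calibrate = FALSE))
      try_path("raking_interview", corrected(vc_int, "interview", calibrate = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("replicate_result", class(out))
  out
}

#' Run a Monte-Carlo simulation study
#'
#' Executes independent replicates (seed `base_seed + i` for replicate `i`,
#' so any single replicate can be re-run in isolation) and aggregates, per
#' estimator and contrast: mean estimate, Monte-Carlo SD, mean reported
#' SE, 95% CI coverage of the configured truth, and the relative
#' Monte-Carlo efficiency of the raking estimator versus plain IPW. Failed
#' replicates are counted and excluded from the aggregates; a study with
#' more than 20% failures is marked unreliable.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates.
#' @param base_seed Base seed.
#' @param verbose Emit a progress message every 50 replicates?
#' @return A `study_report`: list with `replicates` (all rows),
#'   `summary` (per-estimator aggregation), `truth` (true log IRR per
#'   contrast), `n_replicates`, `unreliable`.
#' @export
run_study <- function(truth, design, formula = default_formula(),
                      contrasts = default_contrasts()["implant_efv_vs_nvp"],
                      estimators = ESTIMATORS,
                      n_replicates = 100L, base_seed = 1L, m = 10L,
                      variance = "fixed_weight", verbose = FALSE) {
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    r <- tryCatch(
      run_replicate(truth, design, formula, contrasts, estimators,
                    seed = base_seed + i, m = m, variance = variance),
      error = function(e) {
        data.frame(stratum = NA, contrast = names(contrasts), log_irr = NA_real_,
                   se_log_irr = NA_real_, aIRR = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, estimator = estimators[1L],
                   error = conditionMessage(e))
      })
    r$replicate <- i
    reps[[i]] <- as.data.frame(r)
    if (verbose && i %% 50L == 0L) message("replicate ", i, "/", n_replicates)
  }
  replicates <- do.call(rbind, reps)
  truths <- vapply(contrasts, function(ct) truth_contrast(truth, ct), numeric(1))

  agg <- list()
  for (ctn in names(contrasts)) {
    tr <- truths[[ctn]]
    for (est in unique(replicates$estimator)) {
      sub <- replicates[replicates$estimator == est & replicates$contrast == ctn, ]
      ok <- sub[is.na(sub$error) & is.finite(sub$log_irr), , drop = FALSE]
      agg[[length(agg) + 1L]] <- data.frame(
        contrast = ctn, estimator = est,
        n_ok = nrow(ok), n_failed = nrow(sub) - nrow(ok),
        mean_log_irr = mean(ok$log_irr),
        mc_sd = stats::sd(ok$log_irr),
        mean_se = mean(ok$se_log_irr),
        bias = mean(ok$log_irr) - tr,
        mc_se_of_mean = stats::sd(ok$log_irr) / sqrt(max(nrow(ok), 1L)),
        coverage = mean(ok$ci_low <= exp(tr) & exp(tr) <= ok$ci_high),
        truth_log_irr = tr,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, agg)
  ## relative Monte-Carlo efficiency of raking vs plain IPW, per phase
  for (ph in c("chart", "interview")) {
    rk <- summary[summary$estimator == paste0("raking_", ph), , drop = FALSE]
    iw <- summary[summary$estimator == paste0("ipw_", ph), , drop = FALSE]
    if (nrow(rk) && nrow(iw)) {
      summary[[paste0("releff_raking_vs_ipw_", ph)]] <-
        ifelse(summary$estimator == paste0("raking_", ph),
               (rk$mc_sd[match(summary$contrast, rk$contrast)]^2) /
               (iw$mc_sd[match(summary$contrast, iw$contrast)]^2), NA_real_)
    }
  }
  failed_frac <- sum(summary$n_failed) / max(sum(summary$n_ok + summary$n_failed), 1L)
  structure(list(replicates = replicates, summary = summary, truth = truths,
                 n_replicates = n_replicates, base_seed = base_seed,
                 unreliable = failed_frac > 0.2),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Simulation study: ", x$n_replicates, " replicates",
      if (x$unreliable) " [UNRELIABLE: >20% failures]", "\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Forest plot of rate-ratio estimates (courtesy)
#'
#' @param irr An `irr_table` (rows = contrasts/estimators) with columns
#'   `aIRR`, `ci_low`, `ci_high` and a label column.
#' @param label Name of the label column.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_forest <- function(irr, label = "contrast") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot_forest()")
  }
  irr$.label <- interaction(irr[[label]],
                            if (!is.null(irr$estimator)) irr$estimator else "",
                            drop = TRUE)
  ggplot2::ggplot(irr, ggplot2::aes(x = .data$aIRR, y = .data$.label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Adjusted IRR (log scale)", y = NULL)
}
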