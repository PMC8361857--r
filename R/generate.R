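## Synthetic EMR-like cohort generator with known truth.
##
## Time is handled internally as integer days since the study start; dates
## are materialized only when visit tables are assembled.

.default_rates <- function() {
  ## true pregnancy rates per woman-year by contraceptive x ART cell;
  ## reference cell is NONE x NVP. The implant EFV:NVP ratio is 3.2.
  rbind(
    IMPLANT = c(EFV = 0.048, NVP = 0.015, NO_ART = 0.020),
    DMPA    = c(EFV = 0.035, NVP = 0.030, NO_ART = 0.030),
    NONE    = c(EFV = 0.120, NVP = 0.120, NO_ART = 0.120)
  )
}

.confusion <- function(levels, diag_p, spread = NULL) {
  k <- length(levels)
  m <- matrix(0, k, k, dimnames = list(levels, levels))
  for (i in seq_len(k)) {
    m[i, ] <- (1 - diag_p) / (k - 1)
    m[i, i] <- diag_p
  }
  if (!is.null(spread)) for (nm in names(spread)) m[nm, ] <- spread[[nm]]
  m
}

.default_misclassification <- function(contraceptive_levels, art_levels) {
  contr_emr <- .confusion(contraceptive_levels, 0.95)
  if (all(c("IMPLANT", "DMPA", "NONE") %in% contraceptive_levels)) {
    ## implants under-recorded in the EMR: recorded as DMPA or no method
    contr_emr["IMPLANT", ] <- 0
    contr_emr["IMPLANT", c("IMPLANT", "DMPA", "NONE")] <- c(0.85, 0.08, 0.07)
    contr_emr["DMPA", ] <- 0
    contr_emr["DMPA", c("IMPLANT", "DMPA", "NONE")] <- c(0.03, 0.92, 0.05)
    contr_emr["NONE", ] <- 0
    contr_emr["NONE", c("IMPLANT", "DMPA", "NONE")] <- c(0.02, 0.02, 0.96)
  }
  list(
    emr = list(
      contraceptive = contr_emr,
      art = .confusion(art_levels, 0.95),
      pregnancy = c(fn = 0.10, fp = 0.005)
    ),
    chart = list(
      contraceptive = .confusion(contraceptive_levels, 0.995),
      art = .confusion(art_levels, 0.995),
      pregnancy = c(fn = 0.005, fp = 0.0005)
    ),
    interview = list(
      contraceptive = .confusion(contraceptive_levels, 1),
      art = .confusion(art_levels, 1),
      pregnancy = c(fn = 0, fp = 0)
    )
  )
}

#' Configure the synthetic-cohort generator
#'
#' Bundles every parameter of the generator: cohort size and study window,
#' visit intensity, the true pregnancy-rate surface over contraceptive x
#' ART cells (full-interaction parameterization with `NONE` x `NVP` as the
#' reference), exposure-switching hazards, per-phase misclassification
#' (confusion matrices P(recorded | true) for contraceptive and ART, and
#' false-negative / false-positive report probabilities for pregnancy),
#' covariate missingness rates, and the seed.
#'
#' @param n_women Number of women in the cohort.
#' @param study_start,study_end Study window (coercible to `Date`).
#' @param lookahead_days Days past `study_end` during which pregnancy
#'   reports are still collected.
#' @param visit_rate Mean clinic visits per woman per year.
#' @param rates Matrix of true pregnancy rates per woman-year, rows =
#'   contraceptive categories, columns = ART categories.
#' @param covariate_effects Named numeric vector of log-rate effects for
#'   standardized covariates; supported names: `cd4_100` (per 100 cells/uL
#'   above 450) and `age_10` (per 10 years above 33).
#' @param contraceptive_probs,art_probs Named probabilities for the initial
#'   (and re-drawn) exposure categories; names must match `rates` margins.
#' @param switch_rate_contraceptive,switch_rate_art Per-year hazards of
#'   switching exposure category.
#' @param misclassification Nested list with elements `emr`, `chart`,
#'   `interview`, each holding `contraceptive` and `art` confusion matrices
#'   (rows = truth, rows summing to 1) and a `pregnancy` vector
#'   `c(fn=, fp=)`; defaults degrade the EMR most and leave the interview
#'   error-free.
#' @param interview_art_unsure Probability that the interview records the
#'   ART regimen as "unsure" (reconciliation then falls back to the chart).
#' @param missingness Named vector of completely-at-random per-visit
#'   missingness probabilities for covariates; defaults follow the
#'   magnitudes seen in routine EMR data (up to ~26%).
#' @param reachability Probability that a woman can be reached by phone for
#'   a phase-3 interview.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(n_women = 2000,
                         study_start = "2011-01-01",
                         study_end = "2015-12-31",
                         lookahead_days = 270L,
                         visit_rate = 2,
                         rates = .default_rates(),
                         covariate_effects = c(cd4_100 = 0, age_10 = 0),
                         contraceptive_probs = c(IMPLANT = 0.20, DMPA = 0.25, NONE = 0.55),
                         art_probs = c(EFV = 0.35, NVP = 0.45, NO_ART = 0.20),
                         switch_rate_contraceptive = 0.30,
                         switch_rate_art = 0.20,
                         misclassification = NULL,
                         interview_art_unsure = 0.10,
                         missingness = c(education = 0.257, marital = 0.136,
                                         n_children = 0.256, cd4 = 0.07,
                                         bmi = 0.092, who_stage = 0.007),
                         reachability = 0.9,
                         seed = 1L) {
  stopifnot(n_women >= 1, visit_rate > 0, all(rates >= 0),
            all(missingness >= 0 & missingness < 1))
  contraceptive_probs <- contraceptive_probs / sum(contraceptive_probs)
  art_probs <- art_probs / sum(art_probs)
  stopifnot(setequal(names(contraceptive_probs), rownames(rates)),
            setequal(names(art_probs), colnames(rates)))
  if (is.null(misclassification)) {
    misclassification <- .default_misclassification(rownames(rates), colnames(rates))
  }
  for (ph in misclassification) {
    stopifnot(all(abs(rowSums(ph$contraceptive) - 1) < 1e-8),
              all(abs(rowSums(ph$art) - 1) < 1e-8))
  }
  baseline <- rates["NONE", "NVP"]
  structure(list(
    n_women = as.integer(n_women),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    lookahead_days = as.integer(lookahead_days),
    visit_rate = visit_rate,
    rates = rates,
    baseline_rate = baseline,
    log_rate_effects = log(rates) - log(baseline),
    covariate_effects = covariate_effects,
    contraceptive_probs = contraceptive_probs,
    art_probs = art_probs,
    switch_rate_contraceptive = switch_rate_contraceptive,
    switch_rate_art = switch_rate_art,
    misclassification = misclassification,
    interview_art_unsure = interview_art_unsure,
    missingness = missingness,
    reachability = reachability,
    seed = as.integer(seed)
  ), class = "truth_config")
}

#' Error-free generator configuration
#'
#' A [truth_config()] whose recording phases use identity confusion
#' matrices, no false pregnancy reports or omissions, no interview
#' "unsure" responses, and full phone reachability. Useful as the
#' no-error limit in which naive and corrected estimators must agree.
#'
#' @param n_women Number of women.
#' @param seed Generator seed.
#' @param missingness Named per-covariate MCAR masking rates (default:
#'   none, apart from a zero placeholder).
#' @param ... Further arguments passed to [truth_config()].
#' @return A `truth_config`.
#' @export
identity_truth_config <- function(n_women = 500, seed = 1L,
                                  missingness = c(cd4 = 0), ...) {
  lv_c <- c("IMPLANT", "DMPA", "NONE")
  lv_a <- c("EFV", "NVP", "NO_ART")
  idm <- function(lv) {
    m <- diag(length(lv)); dimnames(m) <- list(lv, lv); m
  }
  phase <- list(contraceptive = idm(lv_c), art = idm(lv_a),
                pregnancy = c(fn = 0, fp = 0))
  truth_config(n_women = n_women, seed = seed,
               misclassification = list(emr = phase, chart = phase,
                                        interview = phase),
               interview_art_unsure = 0,
               missingness = missingness,
               reachability = 1, ...)
}

#' True log incidence-rate-ratio contrast implied by a config
#'
#' @param config A [truth_config()].
#' @param contraceptive Contraceptive stratum of the contrast.
#' @param art_a,art_b ART levels contrasted (a vs b) within the stratum.
#' @return The true within-stratum log rate ratio.
#' @export
true_log_irr <- function(config, contraceptive = "IMPLANT",
                         art_a = "EFV", art_b = "NVP") {
  log(config$rates[contraceptive, art_a]) - log(config$rates[contraceptive, art_b])
}

## raw labels used when materializing category values into visit records
.contr_raw <- c(IMPLANT = "implant_etg", DMPA = "dmpa", OCP = "ocp",
                MEC = "iud", LEC = "condom", NONE = "none")
.art_raw <- c(EFV = "efavirenz;tenofovir;lamivudine",
              NVP = "nevirapine;zidovudine;lamivudine",
              PI = "lopinavir_r;tenofovir;lamivudine",
              NO_ART = "")

## visit-anchored exposure path: the category can change only at a clinic
## visit, with per-visit switch probability 1 - exp(-rate * gap_years).
## Returns the value at each visit and a running segment index (a new
## segment starts at every switch, even when the redrawn category happens
## to repeat, mirroring a fresh prescription).
.visit_path <- function(vdays, probs, switch_rate) {
  nv <- length(vdays)
  lv <- names(probs)
  vals <- character(nv)
  seg <- integer(nv)
  vals[1L] <- sample(lv, 1L, prob = probs)
  seg[1L] <- 1L
  if (nv > 1L) {
    gaps <- diff(vdays) / DAYS_PER_YEAR
    sw <- stats::runif(nv - 1L) < 1 - exp(-switch_rate * gaps)
    draws <- sample(lv, nv - 1L, replace = TRUE, prob = probs)
    for (i in 2:nv) {
      if (sw[i - 1L]) {
        vals[i] <- draws[i - 1L]
        seg[i] <- seg[i - 1L] + 1L
      } else {
        vals[i] <- vals[i - 1L]
        seg[i] <- seg[i - 1L]
      }
    }
  }
  list(values = vals, seg = seg)
}

## conception days under a piecewise-constant intensity on [t0, t1], with a
## 266-day non-risk window after each conception
.sim_conceptions <- function(t0, t1, breaks, lambda) {
  events <- numeric(0)
  t <- t0
  while (t < t1) {
    remaining <- stats::rexp(1)
    repeat {
      k <- findInterval(t, breaks)
      seg_end <- if (k < length(breaks)) breaks[k + 1L] else Inf
      seg_end <- min(seg_end, t1)
      lam <- lambda[k] / DAYS_PER_YEAR  # per day
      if (lam <= 0) {
        if (seg_end >= t1) { t <- t1; break }
        t <- seg_end
        next
      }
      dt <- remaining / lam
      if (t + dt < seg_end) {
        t <- t + dt
        events <- c(events, t)
        t <- t + GESTATION_DAYS  # not at risk during pregnancy
        break
      }
      remaining <- remaining - lam * (seg_end - t)
      t <- seg_end
      if (t >= t1) break
    }
  }
  events[events < t1]
}

## one categorical draw per row of a confusion matrix, given true values
.row_cumsum <- function(m) {
  for (k in seq_len(ncol(m))[-1L]) m[, k] <- m[, k - 1L] + m[, k]
  m
}

## `confusion` must already be row-cumulated (see .row_cumsum)
.misclassify <- function(true_values, confusion) {
  lv <- colnames(confusion)
  u <- stats::runif(length(true_values))
  ri <- match(true_values, rownames(confusion))
  j <- rowSums(u > confusion[ri, , drop = FALSE]) + 1L
  lv[pmin(j, length(lv))]
}

#' Generate a synthetic EMR study with known truth
#'
#' Simulates, per woman: clinic-visit times from a homogeneous Poisson
#' process; piecewise-constant true contraceptive and ART exposures
#' switching at exponential times; incident pregnancies from a
#' piecewise-constant Poisson intensity during at-risk time, with a 38-week
#' non-risk window after each conception; covariates from simple parametric
#' families, masked completely at random. Four visit tables are produced:
#' the gold-standard truth and degraded EMR, chart-review and interview
#' copies, with exposure errors drawn independently per true exposure
#' period from the per-phase confusion matrices, and pregnancy reports
#' dropped (false negatives) or fabricated (false positives) at the
#' per-phase rates.
#'
#' @param config A [truth_config()].
#' @param phases Which visit tables to materialize (each phase consumes its
#'   own fixed random stream, so a table is identical whether or not the
#'   others are built; skipping unneeded phases saves time in simulation
#'   loops).
#' @return An object of class `generated_study`: a list with `truth_visits`,
#'   `emr_visits`, `chart_visits`, `interview_visits` (visit tables sharing
#'   woman ids and visit dates; `NULL` when not requested in `phases`),
#'   `women` (woman-level table with the phone `reachable` flag), and
#'   `config`.
#' @export
generate_cohort <- function(config,
                            phases = c("truth", "emr", "chart", "interview")) {
  phases <- match.arg(phases, several.ok = TRUE)
  stopifnot(inherits(config, "truth_config"))
  set.seed(config$seed)
  D <- as.numeric(config$study_end - config$study_start)
  if (D <= 0) stop("degenerate config: empty study window")
  horizon <- D + config$lookahead_days
  n <- config$n_women
  eff <- config$log_rate_effects
  ce <- config$covariate_effects

  ## woman-level covariates
  age0 <- pmin(pmax(stats::rnorm(n, 33, 6), 16), 45)
  marital <- sample(c("married", "never_married", "separated", "widowed", "cohabiting"),
                    n, TRUE, prob = c(0.557, 0.126, 0.117, 0.19, 0.01))
  education <- sample(c("some_primary", "completed_primary", "some_secondary",
                        "completed_secondary", "some_college", "completed_college", "none"),
                      n, TRUE, prob = c(0.471, 0.187, 0.157, 0.127, 0.043, 0.010, 0.005))
  n_children <- stats::rpois(n, 1.8)
  who_stage <- sample(1:4, n, TRUE, prob = c(0.376, 0.276, 0.287, 0.061))
  cd4_0 <- stats::rlnorm(n, log(450), 0.55)
  weight0 <- pmin(pmax(stats::rnorm(n, 58, 9), 38), 110)
  bmi0 <- pmin(pmax(stats::rnorm(n, 22, 3.2), 14.5), 42)
  anti_tb <- stats::runif(n) < 0.05
  program <- sample(c("AMPATH", "FACES"), n, TRUE, prob = c(0.63, 0.37))
  reachable <- stats::runif(n) < config$reachability
  cov_lp <- ce[["cd4_100"]] * (cd4_0 - 450) / 100 + ce[["age_10"]] * (age0 - 33) / 10

  rows <- vector("list", n)
  for (w in seq_len(n)) {
    nv <- stats::rpois(1, config$visit_rate * horizon / DAYS_PER_YEAR)
    if (nv == 0L) { rows[[w]] <- NULL; next }
    vdays <- sort(unique(floor(stats::runif(nv, 0, horizon))))
    nv <- length(vdays)

    ## true exposures switch only at clinic visits (contraceptive methods
    ## and ART regimens are changed at encounters); the per-visit switch
    ## probability integrates the configured per-year hazard over the gap
    ## since the previous visit
    cpath <- .visit_path(vdays, config$contraceptive_probs,
                         config$switch_rate_contraceptive)
    apath <- .visit_path(vdays, config$art_probs, config$switch_rate_art)
    v_contr <- cpath$values
    v_art <- apath$values
    ci <- cpath$seg
    ai <- apath$seg

    ## pregnancies over observed risk time
    in_win <- vdays <= D
    conceptions <- numeric(0)
    if (sum(in_win) >= 2L) {
      t0 <- min(vdays[in_win]); t1 <- max(vdays[in_win])
      lam <- config$baseline_rate *
        exp(eff[cbind(v_contr, v_art)] + cov_lp[w])
      conceptions <- floor(.sim_conceptions(t0, t1, vdays, lam))
    }
    ## report each conception at the first visit past a detection delay
    report_idx <- rep(NA_integer_, length(conceptions))
    ga_weeks <- lmp_off <- rep(NA_real_, length(conceptions))
    if (length(conceptions)) {
      delays <- floor(stats::runif(length(conceptions), 42, 120))
      for (k in seq_along(conceptions)) {
        i <- match(TRUE, vdays >= conceptions[k] + delays[k])
        if (!is.na(i)) {
          report_idx[k] <- i
          ga_weeks[k] <- (vdays[i] - conceptions[k] + OVULATION_OFFSET) / 7
          lmp_off[k] <- stats::runif(1) < 0.5  # LMP also recalled half the time
        }
      }
      keep <- !is.na(report_idx)
      conceptions <- conceptions[keep]; report_idx <- report_idx[keep]
      ga_weeks <- ga_weeks[keep]; lmp_off <- lmp_off[keep]
    }

    ## time-varying noise on continuous covariates
    cd4_v <- cd4_0[w] * exp(stats::rnorm(nv, 0, 0.10))
    wt_v <- weight0[w] + stats::rnorm(nv, 0, 1.5)
    bmi_v <- bmi0[w] + stats::rnorm(nv, 0, 0.8)

    rows[[w]] <- list(
      woman_id = w, vdays = vdays, contr = v_contr, art = v_art,
      cseg = ci, aseg = ai,
      n_cseg = max(ci), n_aseg = max(ai),
      conceptions = conceptions, report_idx = report_idx,
      ga_weeks = ga_weeks, lmp = as.logical(lmp_off),
      cd4 = cd4_v, weight = wt_v, bmi = bmi_v
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]

  ## assemble a visit table for one phase, applying that phase's errors;
  ## per-woman column lists are concatenated once at the end (building one
  ## data frame per woman is prohibitively slow at cohort scale)
  build_phase <- function(phase = c("truth", "emr", "chart", "interview")) {
    phase <- match.arg(phase)
    mc <- if (phase == "truth") NULL else config$misclassification[[phase]]
    if (!is.null(mc)) {
      mc$contraceptive <- .row_cumsum(mc$contraceptive)
      mc$art <- .row_cumsum(mc$art)
    }
    per_woman <- lapply(rows, function(r) {
      nv <- length(r$vdays)
      if (is.null(mc)) {
        contr <- r$contr; art <- r$art
        rep_i <- r$report_idx; conc <- r$conceptions
        ga <- r$ga_weeks; lmp <- r$lmp
        fp_i <- integer(0)
      } else {
        ## one error draw per true exposure period, constant across its visits
        cvals <- .misclassify(r$contr[!duplicated(r$cseg)], mc$contraceptive)
        avals <- .misclassify(r$art[!duplicated(r$aseg)], mc$art)
        contr <- cvals[match(r$cseg, unique(r$cseg))]
        art <- avals[match(r$aseg, unique(r$aseg))]
        drop <- stats::runif(length(r$report_idx)) < mc$pregnancy[["fn"]]
        rep_i <- r$report_idx[!drop]; conc <- r$conceptions[!drop]
        ga <- r$ga_weeks[!drop]; lmp <- r$lmp[!drop]
        fp_i <- which(stats::runif(nv) < mc$pregnancy[["fp"]])
        fp_i <- setdiff(fp_i, rep_i)
      }
      if (phase == "interview") {
        unsure <- stats::runif(nv) < config$interview_art_unsure
        art[unsure] <- "UNSURE"
      }
      preg <- logical(nv); preg[rep_i] <- TRUE; preg[fp_i] <- TRUE
      ga_col <- rep(NA_real_, nv); ga_col[rep_i] <- ga
      ga_col[fp_i] <- (90 + OVULATION_OFFSET) / 7  # fabricated ~13-week report
      lmp_col <- rep(NA_real_, nv)
      has_lmp <- rep_i[which(lmp)]
      lmp_col[has_lmp] <- conc[which(lmp)] - OVULATION_OFFSET
      out_col <- rep(NA_real_, nv)
      out_col[rep_i] <- conc + GESTATION_DAYS
      list(
        woman_id = rep(r$woman_id, nv), vday = r$vdays,
        contraceptive_codes = unname(.contr_raw[contr]),
        art_drugs = unname(ifelse(art == "UNSURE", "unsure", .art_raw[art])),
        preg_reported = preg, gest_age_weeks = ga_col, lmp_day = lmp_col,
        outcome_day = out_col,
        cd4 = r$cd4, weight = r$weight, bmi = r$bmi
      )
    })
    grab <- function(f) unlist(lapply(per_woman, `[[`, f), use.names = FALSE)
    v <- data.frame(
      woman_id = grab("woman_id"),
      contraceptive_codes = grab("contraceptive_codes"),
      art_drugs = grab("art_drugs"),
      preg_reported = grab("preg_reported"),
      gest_age_weeks = grab("gest_age_weeks"),
      cd4 = grab("cd4"), weight = grab("weight"), bmi = grab("bmi"),
      stringsAsFactors = FALSE
    )
    v$visit_date <- config$study_start + grab("vday")
    v$lmp_date <- config$study_start + grab("lmp_day")
    v$outcome_date <- config$study_start + grab("outcome_day")
    w <- v$woman_id
    v$age <- age0[w] + as.numeric(v$visit_date - config$study_start) / DAYS_PER_YEAR
    v$marital <- marital[w]; v$education <- education[w]
    v$n_children <- n_children[w]; v$who_stage <- who_stage[w]
    v$anti_tb <- anti_tb[w]; v$program <- program[w]
    v
  }

  phase_seed <- c(truth = 1L, emr = 2L, chart = 3L, interview = 4L)
  tables <- list(truth = NULL, emr = NULL, chart = NULL, interview = NULL)
  for (ph in phases) {
    set.seed(config$seed + phase_seed[[ph]])
    tables[[ph]] <- build_phase(ph)
  }
  truth_visits <- tables$truth
  emr_visits <- tables$emr
  chart_visits <- tables$chart
  interview_visits <- tables$interview

  ## completely-at-random covariate masking in the EMR
  if (!is.null(emr_visits)) {
    set.seed(config$seed + 5L)
    for (v in names(config$missingness)) {
      if (!v %in% names(emr_visits)) next
      mask <- stats::runif(nrow(emr_visits)) < config$missingness[[v]]
      emr_visits[[v]][mask] <- NA
    }
  }

  structure(list(
    truth_visits = truth_visits, emr_visits = emr_visits,
    chart_visits = chart_visits, interview_visits = interview_visits,
    women = data.frame(woman_id = seq_len(n), reachable = reachable,
                       program = program, stringsAsFactors = FALSE),
    config = config
  ), class = "generated_study")
}

#' @export
print.generated_study <- function(x, ...) {
  cat("Synthetic EMR study: ", x$config$n_women, " women",
      if (!is.null(x$emr_visits)) paste0(", ", nrow(x$emr_visits), " EMR visits"),
      if (!is.null(x$truth_visits))
        paste0(", ", sum(x$truth_visits$preg_reported), " true reported pregnancies"),
      "\n", sep = "")
  invisible(x)
}

#' Person-years and pregnancy counts by exposure cell
#'
#' Tabulates incident pregnancies and women-years of observation by
#' contraceptive x ART cell from coded observation periods.
#'
#' @param x A `coded_cohort` or a periods data frame.
#' @return Data frame with columns `contraceptive`, `art`, `pregnancies`,
#'   `women_years`.
#' @export
summarize_cohort <- function(x) {
  periods <- if (inherits(x, "coded_cohort")) x$periods else x
  if (nrow(periods) == 0L) {
    return(data.frame(contraceptive = character(0), art = character(0),
                      pregnancies = integer(0), women_years = numeric(0)))
  }
  ag <- stats::aggregate(cbind(pregnancies = periods$pregnancy,
                               women_years = periods$exposure_time),
                         by = list(contraceptive = periods$contraceptive,
                                   art = periods$art),
                         FUN = sum)
  ag[order(ag$contraceptive, ag$art), , drop = FALSE]
}
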