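## Phase-2 stratified validation sampling, phase-3 priority sampling,
## inclusion probabilities, and cross-phase record reconciliation.

PHASE2_CONTRACEPTIVE <- c("IMPLANT", "DMPA", "MEC", "NONE")
PHASE2_ART <- c("EFV", "NVP", "PI", "NO_ART")

#' Enumerate the 32 phase-2 sampling strata
#'
#' The cross of contraceptive (implant, DMPA, MEC, none) x ART (efavirenz,
#' nevirapine, PI, no ART) x pregnancy status (yes/no). Stratum labels are
#' `"<CONTRACEPTIVE>.<ART>.<0|1>"`; women whose exposures never fall in the
#' 4 x 4 grid go to a catch-all `"OTHER"` stratum.
#'
#' @return Character vector of the 32 stratum labels.
#' @export
phase2_strata <- function() {
  g <- expand.grid(contraceptive = PHASE2_CONTRACEPTIVE, art = PHASE2_ART,
                   pregnancy = 0:1, stringsAsFactors = FALSE)
  paste(g$contraceptive, g$art, g$pregnancy, sep = ".")
}

#' Assign each woman to a validation-sampling stratum
#'
#' Charts and interviews are per woman, so sampling units are women, not
#' periods. A woman whose periods span several contraceptive x ART cells is
#' assigned to the cell she occupies that is rarest in the cohort
#' (woman-level frequency of the (contraceptive, ART, pregnancy-in-cell)
#' triple), which naturally prioritizes the scarce cells of interest such as
#' pregnant implant users. Women with no period in the 4 x 4 grid are
#' labelled `OTHER`.
#'
#' @param periods Coded observation periods (or a `coded_cohort`).
#' @return Data frame with one row per woman: `woman_id`, `stratum`,
#'   `contraceptive`, `art`, `pregnant`.
#' @export
assign_strata <- function(periods) {
  if (inherits(periods, "coded_cohort")) periods <- periods$periods
  ## per-woman cell table with pregnancy-in-cell indicator
  key <- paste(periods$woman_id, periods$contraceptive, periods$art, sep = "\r")
  preg <- tapply(periods$pregnancy, key, max)
  parts <- strsplit(names(preg), "\r", fixed = TRUE)
  cells <- data.frame(
    woman_id = vapply(parts, `[[`, "", 1L),
    contraceptive = vapply(parts, `[[`, "", 2L),
    art = vapply(parts, `[[`, "", 3L),
    pregnant = as.integer(preg),
    stringsAsFactors = FALSE
  )
  in_grid <- cells$contraceptive %in% PHASE2_CONTRACEPTIVE & cells$art %in% PHASE2_ART
  grid_cells <- cells[in_grid, , drop = FALSE]
  grid_cells$stratum <- paste(grid_cells$contraceptive, grid_cells$art,
                              grid_cells$pregnant, sep = ".")
  freq <- table(grid_cells$stratum)
  grid_cells$freq <- as.integer(freq[grid_cells$stratum])
  ## pick, per woman, her rarest triple (ties: pregnant first, then label)
  o <- order(grid_cells$woman_id, grid_cells$freq, -grid_cells$pregnant,
             grid_cells$stratum)
  grid_cells <- grid_cells[o, , drop = FALSE]
  chosen <- grid_cells[!duplicated(grid_cells$woman_id), , drop = FALSE]

  all_women <- unique(as.character(periods$woman_id))
  out <- data.frame(woman_id = all_women, stratum = "OTHER",
                    contraceptive = NA_character_, art = NA_character_,
                    pregnant = 0L, stringsAsFactors = FALSE)
  m <- match(chosen$woman_id, out$woman_id)
  out$stratum[m] <- chosen$stratum
  out$contraceptive[m] <- chosen$contraceptive
  out$art[m] <- chosen$art
  out$pregnant[m] <- chosen$pregnant
  ## women in OTHER may still have had a pregnancy
  other <- out$stratum == "OTHER"
  if (any(other)) {
    any_preg <- tapply(periods$pregnancy, as.character(periods$woman_id), max)
    out$pregnant[other] <- as.integer(any_preg[out$woman_id[other]])
  }
  rownames(out) <- NULL
  out
}

#' Specify the validation-sampling design
#'
#' @param phase2_fractions Named numeric vector of phase-2 sampling
#'   fractions. Names are stratum labels (see [phase2_strata()]); the
#'   reserved name `".default"` supplies the fraction for unnamed strata
#'   (including `OTHER`). Glob-free prefix matching is not performed;
#'   strata are matched exactly.
#' @param phase2_targets Optional named integer vector of absolute
#'   per-stratum sample sizes; overrides fractions where named. Targets
#'   exceeding the stratum size are capped with a warning.
#' @param phase2_min Minimum number sampled from every non-empty stratum
#'   (capped at the stratum size).
#' @param phase3_priority Ordered woman-level priority categories for the
#'   interview phase.
#' @param phase3_budget Maximum number of interviews.
#' @param p2_floor Lower clip for fitted phase-3 inclusion probabilities,
#'   bounding the weights.
#' @param seed Integer seed making both sampling phases reproducible.
#' @return An object of class `sampling_design`.
#' @export
sampling_design <- function(phase2_fractions = default_phase2_fractions(),
                            phase2_targets = NULL,
                            phase2_min = 2L,
                            phase3_priority = c("pregnant_implant", "nonpregnant_implant",
                                                "pregnant_dmpa", "nonpregnant_dmpa", "other"),
                            phase3_budget = 100L,
                            p2_floor = 1e-3,
                            seed = 1L) {
  stopifnot(is.numeric(phase2_fractions), ".default" %in% names(phase2_fractions),
            all(phase2_fractions >= 0 & phase2_fractions <= 1))
  structure(list(phase2_fractions = phase2_fractions,
                 phase2_targets = phase2_targets,
                 phase2_min = as.integer(phase2_min),
                 phase3_priority = phase3_priority,
                 phase3_budget = as.integer(phase3_budget),
                 p2_floor = p2_floor,
                 seed = as.integer(seed)),
            class = "sampling_design")
}

#' Default (illustrative) phase-2 sampling fractions
#'
#' Heavily over-samples pregnant implant users, then pregnant DMPA users,
#' then non-pregnant implant users, with a small default fraction
#' elsewhere; with the default generator this validates roughly 6% of
#' women. These fractions are an example design, not a reproduction of any
#' realized study.
#'
#' @return Named numeric vector of fractions with a `".default"` entry.
#' @export
default_phase2_fractions <- function() {
  fr <- c(.default = 0.015)
  for (a in PHASE2_ART) {
    fr[paste("IMPLANT", a, 1, sep = ".")] <- 1.0
    fr[paste("DMPA", a, 1, sep = ".")] <- 0.5
    fr[paste("IMPLANT", a, 0, sep = ".")] <- 0.05
    fr[paste("DMPA", a, 0, sep = ".")] <- 0.02
  }
  fr
}

## per-stratum realized target sizes
.phase2_targets <- function(counts, design) {
  sizes <- integer(length(counts))
  names(sizes) <- names(counts)
  for (s in names(counts)) {
    N <- counts[[s]]
    if (!is.null(design$phase2_targets) && s %in% names(design$phase2_targets)) {
      n <- design$phase2_targets[[s]]
      if (n > N) {
        warning("stratum ", s, ": target ", n, " exceeds size ", N, "; capped")
        n <- N
      }
    } else {
      fr <- design$phase2_fractions
      f <- if (s %in% names(fr)) fr[[s]] else fr[[".default"]]
      n <- round(f * N)
      n <- max(n, min(design$phase2_min, N))
    }
    sizes[[s]] <- as.integer(min(n, N))
  }
  sizes
}

#' Draw the phase-2 (chart review) sample
#'
#' Simple random sampling without replacement within each stratum at the
#' design's target size. The inclusion probability `p1` is the realized
#' per-stratum sampling fraction (number sampled / stratum size). Strata
#' sampled 0 of >0 are flagged: their members have `p1 = 0` and are
#' excluded from weighted analyses.
#'
#' @param strata Woman-level stratum table from [assign_strata()].
#' @param design A [sampling_design()].
#' @param seed Seed (defaults to the design's).
#' @return Data frame of sample assignments: `woman_id`, `stratum`,
#'   `sampled_phase2`, `p1`, `weight_phase2`.
#' @export
sample_phase2 <- function(strata, design, seed = design$seed) {
  set.seed(seed)
  counts <- table(strata$stratum)
  targets <- .phase2_targets(counts, design)
  sampled <- logical(nrow(strata))
  for (s in names(targets)) {
    idx <- which(strata$stratum == s)
    if (targets[[s]] > 0L) {
      sampled[idx[sample.int(length(idx), targets[[s]])]] <- TRUE
    } else if (length(idx) > 0L) {
      message("stratum ", s, " sampled 0 of ", length(idx),
              "; its members carry no weight")
    }
  }
  p1 <- as.numeric(targets[strata$stratum] / counts[strata$stratum])
  out <- strata
  out$sampled_phase2 <- sampled
  out$p1 <- p1
  out$weight_phase2 <- ifelse(sampled & p1 > 0, 1 / p1, NA_real_)
  out
}

#' Phase-3 priority category of a woman
#'
#' @param strata Woman-level stratum table (needs `contraceptive`,
#'   `pregnant`).
#' @return Character vector among `pregnant_implant`, `nonpregnant_implant`,
#'   `pregnant_dmpa`, `nonpregnant_dmpa`, `other`.
#' @export
priority_category <- function(strata) {
  ifelse(!is.na(strata$contraceptive) & strata$contraceptive == "IMPLANT",
         ifelse(strata$pregnant == 1, "pregnant_implant", "nonpregnant_implant"),
  ifelse(!is.na(strata$contraceptive) & strata$contraceptive == "DMPA",
         ifelse(strata$pregnant == 1, "pregnant_dmpa", "nonpregnant_dmpa"),
         "other"))
}

#' Draw the phase-3 (telephone interview) sample
#'
#' Among phase-2 women, interviews are allocated by priority category in
#' the design's order (pregnant implant users first) until the budget is
#' exhausted; within a category the order is random. Only reachable women
#' (working phone) can be interviewed. The phase-3 inclusion probability
#' `p2` is then fitted with [fit_p2_model()].
#'
#' @param assignments Output of [sample_phase2()].
#' @param design A [sampling_design()].
#' @param reachable Optional logical vector (or data frame with `woman_id`,
#'   `reachable`) marking women reachable by phone; defaults to all.
#' @param seed Seed (defaults to the design's seed + 1).
#' @return `assignments` with `priority_cat`, `sampled_phase3`, `p2` and
#'   `weight_phase3 = 1/(p1*p2)` columns added.
#' @export
sample_phase3 <- function(assignments, design, reachable = NULL,
                          seed = design$seed + 1L) {
  set.seed(seed)
  assignments$priority_cat <- priority_category(assignments)
  if (is.null(reachable)) {
    reach <- rep(TRUE, nrow(assignments))
  } else if (is.data.frame(reachable)) {
    reach <- reachable$reachable[match(assignments$woman_id, reachable$woman_id)]
    reach[is.na(reach)] <- FALSE
  } else {
    reach <- reachable
  }
  eligible <- which(assignments$sampled_phase2 & reach)
  sel <- integer(0)
  budget <- design$phase3_budget
  for (cat in design$phase3_priority) {
    if (budget <= 0L) break
    pool <- eligible[assignments$priority_cat[eligible] == cat]
    pool <- setdiff(pool, sel)
    if (length(pool) == 0L) next
    take <- min(budget, length(pool))
    pick <- if (take == length(pool)) pool else pool[sample.int(length(pool), take)]
    sel <- c(sel, pick)
    budget <- budget - take
  }
  assignments$sampled_phase3 <- FALSE
  assignments$sampled_phase3[sel] <- TRUE
  assignments <- fit_p2_model(assignments, p2_floor = design$p2_floor)
  assignments
}

#' Fit phase-3 inclusion probabilities p2
#'
#' Logistic regression of phase-3 selection on the priority-category
#' indicators, among phase-2 women. Under perfect separation (categories
#' taken in full or not at all, which the budgeted priority rule routinely
#' produces) the fit falls back to the empirical per-category selection
#' fractions, which coincide with the saturated-model estimates. Fitted
#' probabilities are clipped to `[p2_floor, 1]`.
#'
#' @param assignments Assignment table with `sampled_phase2`,
#'   `sampled_phase3` and `priority_cat` columns.
#' @param p2_floor Lower clip bounding the weights.
#' @return `assignments` with `p2` and `weight_phase3` columns.
#' @export
fit_p2_model <- function(assignments, p2_floor = 1e-3) {
  ph2 <- which(assignments$sampled_phase2)
  if (length(ph2) == 0L) stop("no phase-2 sample; cannot fit p2")
  y <- assignments$sampled_phase3[ph2]
  cat <- factor(assignments$priority_cat[ph2])
  p2 <- rep(NA_real_, nrow(assignments))
  frac <- tapply(y, cat, mean)
  fitted <- tryCatch({
    fit <- suppressWarnings(stats::glm(y ~ cat, family = stats::binomial()))
    f <- stats::fitted(fit)
    ## separation check: fall back when the MLE diverges from the
    ## empirical category fractions
    if (max(abs(f - frac[as.character(cat)])) > 1e-4) stop("separation")
    f
  }, error = function(e) {
    warning("p2 logistic model degenerate (separation); using empirical ",
            "category fractions")
    as.numeric(frac[as.character(cat)])
  })
  p2[ph2] <- pmin(pmax(fitted, p2_floor), 1)
  assignments$p2 <- p2
  assignments$weight_phase3 <- ifelse(
    assignments$sampled_phase3 & !is.na(p2),
    1 / (assignments$p1 * p2), NA_real_)
  assignments
}

#' Reconcile EMR, chart-review and interview records
#'
#' For the validated variables (contraceptive method, ART regimen,
#' pregnancy report) the interview value takes precedence over the chart
#' value, which takes precedence over the EMR; for ART only, an interview
#' response of "unsure" falls back to the chart value. Chart or interview
#' observation time outside the woman's EMR observation window is trimmed.
#' Only women in `women` (typically the phase-2 or phase-3 sample) are
#' reconciled; every interview woman must have a chart record (three-phase
#' nesting), otherwise this is an error.
#'
#' @param emr_visits,chart_visits Visit tables; `chart_visits` covers the
#'   chart-reviewed women.
#' @param interview_visits Optional visit table for interviewed women.
#' @param women Character/integer vector of woman ids to reconcile
#'   (default: all women present in `chart_visits`).
#' @return A list with `visits` (reconciled visit table, ready for
#'   [code_cohort()]) and `detail` (per-visit provenance of each validated
#'   variable).
#' @export
reconcile <- function(emr_visits, chart_visits, interview_visits = NULL,
                      women = unique(chart_visits$woman_id)) {
  if (!is.null(interview_visits)) {
    orphan <- setdiff(unique(interview_visits$woman_id),
                      unique(chart_visits$woman_id))
    orphan <- intersect(orphan, women)
    if (length(orphan)) {
      stop("interview records without matching chart review (three-phase ",
           "nesting violated) for women: ",
           paste(utils::head(orphan, 5L), collapse = ", "))
    }
  }
  emr <- emr_visits[emr_visits$woman_id %in% women, , drop = FALSE]
  key <- function(v) paste(v$woman_id, as.Date(v$visit_date), sep = "\r")

  ## EMR observation window per woman, for trimming
  emr_d <- as.Date(emr$visit_date)
  win_lo <- tapply(as.numeric(emr_d), emr$woman_id, min)
  win_hi <- tapply(as.numeric(emr_d), emr$woman_id, max)
  trim <- function(v) {
    v <- v[v$woman_id %in% women, , drop = FALSE]
    d <- as.numeric(as.Date(v$visit_date))
    lo <- win_lo[as.character(v$woman_id)]
    hi <- win_hi[as.character(v$woman_id)]
    keep <- !is.na(lo) & d >= lo & d <= hi
    v[keep, , drop = FALSE]
  }
  chart <- trim(chart_visits)
  interview <- if (is.null(interview_visits)) NULL else trim(interview_visits)

  out <- emr
  preg_cols <- intersect(c("preg_reported", "gest_age_weeks", "lmp_date",
                           "edd_date", "outcome_date"), names(emr))
  src_contr <- rep("EMR", nrow(out))
  src_art <- rep("EMR", nrow(out))
  src_preg <- rep("EMR", nrow(out))

  apply_phase <- function(phase_visits, label) {
    m <- match(key(out), key(phase_visits))
    hit <- !is.na(m)
    out$contraceptive_codes[hit] <<- phase_visits$contraceptive_codes[m[hit]]
    src_contr[hit] <<- label
    ## ART: an interview "unsure" does not overwrite the chart value
    art_new <- phase_visits$art_drugs[m[hit]]
    usable <- !(label == "INTERVIEW" & art_new %in% "unsure")
    out$art_drugs[hit][usable] <<- art_new[usable]
    src_art[hit][usable] <<- label
    for (cl in preg_cols) out[[cl]][hit] <<- phase_visits[[cl]][m[hit]]
    src_preg[hit] <<- label
    ## visits present in this phase (inside the EMR window) but absent
    ## from the running table are appended
    extra <- setdiff(key(phase_visits), key(out))
    if (length(extra)) {
      add <- phase_visits[key(phase_visits) %in% extra, , drop = FALSE]
      add <- add[, intersect(names(out), names(add)), drop = FALSE]
      for (cl in setdiff(names(out), names(add))) add[[cl]] <- NA
      out <<- rbind(out, add[, names(out), drop = FALSE])
      src_contr <<- c(src_contr, rep(label, nrow(add)))
      src_art <<- c(src_art, rep(label, nrow(add)))
      src_preg <<- c(src_preg, rep(label, nrow(add)))
    }
  }
  apply_phase(chart, "CHART")
  if (!is.null(interview)) apply_phase(interview, "INTERVIEW")

  o <- order(out$woman_id, as.Date(out$visit_date))
  detail <- data.frame(woman_id = out$woman_id,
                       visit_date = as.Date(out$visit_date),
                       source_contraceptive = src_contr,
                       source_art = src_art,
                       source_pregnancy = src_preg,
                       stringsAsFactors = FALSE)[o, , drop = FALSE]
  out <- out[o, , drop = FALSE]
  ## stale precomputed categories would no longer match the raw fields
  out$contraceptive_category <- NULL
  out$art_category <- NULL
  rownames(out) <- rownames(detail) <- NULL
  list(visits = out, detail = detail)
}

#' Reconcile and re-code validated records into observation periods
#'
#' Convenience wrapper: [reconcile()] then [code_cohort()], so corrected
#' exposures redefine the period boundaries.
#'
#' @inheritParams reconcile
#' @inheritParams code_cohort
#' @return A `coded_cohort` with provenance `"RECONCILED"`.
#' @export
validated_cohort <- function(emr_visits, chart_visits, interview_visits = NULL,
                             women = unique(chart_visits$woman_id),
                             censor_rule = "FIXED_38_WEEKS",
                             study_end = max(as.Date(emr_visits$visit_date)),
                             lookahead_days = 270L) {
  rec <- reconcile(emr_visits, chart_visits, interview_visits, women)
  code_cohort(rec$visits, censor_rule = censor_rule, study_end = study_end,
              lookahead_days = lookahead_days, provenance = "RECONCILED")
}
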