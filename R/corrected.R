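## The corrected (validation-weighted, raking-calibrated) estimator.

#' Raking-calibrated weighted Poisson fit on validated data
#'
#' Implements the correction pipeline: base design weights `1/p1` (chart
#' analyses) or `1/(p1*p2)` (interview analyses); generalized raking of
#' those weights against the per-woman influence functions of the Poisson
#' model fit to the full error-prone cohort (plus a constant column); and a
#' weighted Poisson fit on the validated (reconciled) periods with
#' cluster-robust variance. Under missing-at-random validation sampling
#' with correctly specified sampling models, the resulting adjusted rate
#' ratios consistently estimate what full validation of the cohort would
#' give.
#'
#' Two variance estimators are available. `"calibrated"` propagates the
#' two-phase structure: the phase-2 sandwich uses the calibration
#' residuals (validated score contributions minus their projection on the
#' auxiliaries), added to the phase-1 covariance of the full-cohort fit;
#' this reflects the efficiency gained by calibration. `"fixed_weight"`
#' treats the calibrated weights as fixed in an ordinary cluster-robust
#' sandwich; it ignores the calibration step and is typically conservative.
#'
#' @param validated_periods Reconciled, re-coded periods for the sampled
#'   women (data frame or `coded_cohort`).
#' @param assignments Sample assignments from [sample_phase2()] /
#'   [sample_phase3()] carrying `p1` (and `p2`).
#' @param phase1_fit `poisson_fit` (or `pooled_fit`) on the full cohort's
#'   error-prone periods; supplies the auxiliary influence functions.
#' @param formula Model formula (must match the phase-1 fit's
#'   parameterization for the calibrated variance to be meaningful).
#' @param phase `"chart"` (phase-2 weights) or `"interview"` (phase-3
#'   weights).
#' @param calibrate Apply generalized raking? `FALSE` gives the plain IPW
#'   estimator.
#' @param variance Variance estimator (see Details).
#' @param aux_projection Optional matrix (rows aligned with the phase-1
#'   coefficients) projecting the influence functions onto a smaller
#'   auxiliary set, e.g. [contrast_matrix()] for the target contrasts.
#'   `NULL` calibrates to the full influence-function vector. With small
#'   validation samples the full vector can over-fit the calibration (one
#'   constraint per coefficient), inflating the estimator's variance;
#'   projecting onto the contrasts of interest retains the efficiency gain
#'   where it matters.
#' @param ... Passed to [fit_poisson_robust()].
#' @return A `poisson_fit` with extra elements `raking`
#'   (the [raking_calibrate()] result, when calibrated), `phase`,
#'   `woman_weights`.
#' @export
weighted_corrected_fit <- function(validated_periods, assignments, phase1_fit,
                                   formula = default_formula(),
                                   phase = c("chart", "interview"),
                                   calibrate = TRUE,
                                   variance = c("calibrated", "fixed_weight"),
                                   aux_projection = NULL,
                                   ...) {
  phase <- match.arg(phase)
  variance <- match.arg(variance)
  if (inherits(validated_periods, "coded_cohort")) {
    validated_periods <- validated_periods$periods
  }
  flag <- if (phase == "chart") assignments$sampled_phase2 else assignments$sampled_phase3
  wcol <- if (phase == "chart") assignments$weight_phase2 else assignments$weight_phase3
  sampled <- assignments[which(flag & !is.na(wcol) & is.finite(wcol)), , drop = FALSE]
  d <- wcol[which(flag & !is.na(wcol) & is.finite(wcol))]
  names(d) <- as.character(sampled$woman_id)

  periods <- validated_periods[as.character(validated_periods$woman_id) %in% names(d), , drop = FALSE]
  if (nrow(periods) == 0L) stop("no validated periods for the sampled women")

  raking <- NULL
  if (calibrate) {
    infl <- phase1_fit$influence
    if (!is.null(aux_projection)) {
      aux_projection <- as.matrix(aux_projection)
      if (nrow(aux_projection) != ncol(infl)) {
        stop("aux_projection must have one row per phase-1 coefficient")
      }
      infl <- infl %*% aux_projection
    }
    h_full <- cbind(`(const)` = 1, infl)
    totals <- colSums(h_full)
    ids <- intersect(names(d), rownames(infl))
    if (length(ids) < length(d)) {
      stop("sampled women missing from the phase-1 influence functions: ",
           paste(utils::head(setdiff(names(d), ids), 5L), collapse = ", "))
    }
    h_s <- h_full[names(d), , drop = FALSE]
    raking <- raking_calibrate(d, h_s, totals)
    w_woman <- raking$weights
  } else {
    w_woman <- d
  }
  names(w_woman) <- names(d)

  w_period <- w_woman[as.character(periods$woman_id)]
  fit <- fit_poisson_robust(periods, formula = formula, weights = unname(w_period), ...)

  if (calibrate && variance == "calibrated") {
    ## two-phase variance: phase-1 covariance of the full-cohort estimator
    ## plus the design variance of the calibration residuals
    ids_fit <- rownames(fit$influence)
    U <- fit$influence %*% solve(fit$A_inv)  # cluster score sums, w-weighted
    ww <- w_woman[ids_fit]
    Uw <- U / ww                             # unweighted cluster scores
    hw <- h_full[ids_fit, raking$kept, drop = FALSE]
    ## weighted regression of validated cluster scores on the auxiliaries
    Bmat <- tryCatch(
      solve(crossprod(hw, hw * ww), crossprod(hw, Uw * ww)),
      error = function(e) matrix(0, ncol(hw), ncol(Uw)))
    E <- Uw - hw %*% Bmat
    meat <- crossprod(E * sqrt(pmax(ww * (ww - 1), 0)))
    phase2_v <- fit$A_inv %*% meat %*% fit$A_inv
    ## map the phase-1 covariance onto this fit's parameterization
    if (!identical(colnames(phase1_fit$influence), names(fit$beta))) {
      stop("phase-1 and validated fits have different parameterizations; ",
           "calibrated variance unavailable")
    }
    fit$vcov_robust <- phase1_fit$vcov_robust + phase2_v
    fit$variance <- "calibrated"
  } else {
    fit$variance <- if (calibrate) "fixed_weight" else "ipw_sandwich"
  }
  fit$raking <- raking
  fit$phase <- phase
  fit$woman_weights <- w_woman
  fit
}
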