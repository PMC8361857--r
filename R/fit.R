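## Poisson rate models with cluster-robust (sandwich) variance and
## per-woman influence functions, plus within-stratum rate-ratio contrasts.

#' Prepare coded periods for model fitting
#'
#' Drops periods in excluded exposure categories (by default the sparse
#' `NRTI_ONLY` and `COMBINATION` ART categories and anything still coded
#' `MISSING` after imputation), converts the exposure columns to factors
#' with the requested reference levels (nevirapine-containing ART is the
#' conventional reference), and checks that exposure time is positive.
#'
#' @param periods Periods data frame or `coded_cohort`.
#' @param drop_art ART categories removed before fitting (configurable; PI
#'   is retained by default).
#' @param drop_contraceptive Contraceptive categories removed before
#'   fitting.
#' @param ref_art,ref_contraceptive Reference levels.
#' @return The filtered data frame with `contraceptive` and `art` as
#'   factors.
#' @export
prepare_periods <- function(periods,
                            drop_art = c("NRTI_ONLY", "COMBINATION", "MISSING"),
                            drop_contraceptive = "MISSING",
                            ref_art = "NVP", ref_contraceptive = "NONE") {
  if (inherits(periods, "coded_cohort")) periods <- periods$periods
  keep <- !(periods$art %in% drop_art) & !(periods$contraceptive %in% drop_contraceptive)
  p <- periods[keep, , drop = FALSE]
  stopifnot(all(p$exposure_time > 0))
  c_lev <- intersect(c(ref_contraceptive, CONTRACEPTIVE_LEVELS), unique(p$contraceptive))
  a_lev <- intersect(c(ref_art, ART_LEVELS), unique(p$art))
  p$contraceptive <- factor(p$contraceptive, levels = c_lev)
  p$art <- factor(p$art, levels = a_lev)
  rownames(p) <- NULL
  p
}

#' Model formula in the style of the full covariate-adjusted analysis
#'
#' Full contraceptive x ART interaction plus, optionally, program, average
#' age and its square, marital status, education, an any-children
#' indicator, WHO stage, CD4 and its square root, log BMI and the square
#' root of log BMI, anti-TB treatment, and calendar time.
#'
#' @param covariates Include the covariate terms?
#' @return A formula with `pregnancy` as outcome (the log exposure-time
#'   offset is added by [fit_poisson_robust()]).
#' @export
default_formula <- function(covariates = FALSE) {
  if (!covariates) return(pregnancy ~ contraceptive * art)
  pregnancy ~ contraceptive * art + program + avg_age + I(avg_age^2) +
    marital + education + I(n_children > 0) + factor(who_stage) +
    cd4 + I(sqrt(cd4)) + I(log(bmi)) + I(sqrt(log(bmi))) + anti_tb +
    calendar_year
}

#' Fit a Poisson rate model with cluster-robust variance
#'
#' Maximum (pseudo-)likelihood estimation of a log-linear incidence model
#' with offset `log(exposure_time)`, by iteratively reweighted least
#' squares with step-halving. The variance is the sandwich A^-1 B A^-1
#' with A the (weighted) expected information and B the outer-product sum
#' of cluster-summed weighted scores, clustered by woman; per-woman
#' influence functions A^-1 U_i are returned and sum to zero at the
#' estimate.
#'
#' @param data Periods data frame (see [prepare_periods()]).
#' @param formula Model formula for the pregnancy indicator; exposure
#'   offset is implicit.
#' @param weights Optional positive per-period weights.
#' @param cluster Name of the clustering (woman id) column.
#' @param offset_var Name of the exposure-time column (years).
#' @param tol Convergence tolerance on the deviance change.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `poisson_fit` with elements `beta`,
#'   `vcov_robust`, `influence` (matrix, one row per woman), `A_inv`,
#'   `n_clusters`, `converged`, `iterations`, `loglik`, `fitted`, `terms`,
#'   `xlevels`.
#' @export
fit_poisson_robust <- function(data, formula = default_formula(),
                               weights = NULL, cluster = "woman_id",
                               offset_var = "exposure_time",
                               tol = 1e-10, maxit = 100L) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  if (anyNA(mf)) {
    bad <- names(mf)[vapply(mf, anyNA, logical(1))]
    stop("missing values in model variables (impute first): ",
         paste(bad, collapse = ", "))
  }
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  off <- log(data[[offset_var]])
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  stopifnot(length(w) == nrow(X), all(w > 0), all(is.finite(off)))

  qr_x <- qr(X * sqrt(w))
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient (empty factor cell?): ",
         paste(aliased, collapse = ", "))
  }

  ## IRLS with step-halving
  beta <- numeric(ncol(X))
  beta[1L] <- log(sum(w * y) / sum(w * exp(off)))
  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  dev_fun <- function(mu) {
    r <- w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    2 * sum(r)
  }
  dev <- dev_fun(mu)
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    z <- (eta - off) + (y - mu) / mu
    wls <- w * mu
    fit <- stats::lm.wfit(X, z, wls)
    beta_new <- fit$coefficients
    step <- 1
    repeat {
      b <- beta + step * (beta_new - beta)
      eta_new <- drop(X %*% b) + off
      mu_new <- exp(eta_new)
      dev_new <- dev_fun(mu_new)
      if (is.finite(dev_new) && (dev_new <= dev + 1e-12 || step < 1e-8)) break
      step <- step / 2
    }
    delta <- abs(dev - dev_new)
    beta <- b; eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (delta < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("IRLS did not converge in ", maxit, " iterations (deviance ",
         format(dev), ")")
  }

  ## sandwich pieces
  A <- crossprod(X, X * (w * mu))
  A_inv <- chol2inv(chol(A))
  score_rows <- X * (w * (y - mu))
  cl <- factor(data[[cluster]])
  U <- rowsum(score_rows, cl)            # cluster-summed scores
  B <- crossprod(U)
  vcov_robust <- A_inv %*% B %*% A_inv
  influence <- U %*% A_inv
  colnames(influence) <- colnames(X)
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(
    beta = beta,
    vcov_robust = vcov_robust,
    influence = influence,
    A_inv = A_inv,
    n_clusters = nlevels(cl),
    converged = converged,
    iterations = iter,
    deviance = dev,
    loglik = sum(w * (y * eta - mu - lgamma(y + 1))),
    fitted = mu,
    formula = formula,
    terms = stats::terms(mf),
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    cluster = cluster,
    offset_var = offset_var,
    weights = w
  ), class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("Poisson rate model (cluster-robust), ", x$n_clusters, " clusters, ",
      x$iterations, " IRLS iterations\n", sep = "")
  se <- sqrt(diag(x$vcov_robust))
  print(data.frame(estimate = x$beta, robust_se = se,
                   rate_ratio = exp(x$beta)), digits = 4)
  invisible(x)
}

#' @export
coef.poisson_fit <- function(object, ...) object$beta

#' @export
vcov.poisson_fit <- function(object, ...) object$vcov_robust

## model-matrix row for a synthetic cell, used to build contrast vectors
.cell_row <- function(fit, data_row) {
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, data_row, xlev = fit$xlevels)
  stats::model.matrix(tt, mf)[1L, ]
}

#' Within-stratum adjusted incidence-rate-ratio contrasts
#'
#' For each requested contrast, forms the linear combination of main-effect
#' and interaction coefficients giving the within-stratum log rate ratio
#' (e.g. efavirenz vs nevirapine among implant users, or DMPA vs implant
#' among efavirenz users), with its sandwich standard error and 95% CI.
#' Covariate terms cancel in the within-stratum difference.
#'
#' @param fit A `poisson_fit` (or `pooled_fit`).
#' @param contrasts A list of contrast specifications, each a list with
#'   `stratum_var`, `stratum`, `var`, `a`, `b`: the rate ratio compares
#'   `var = a` vs `var = b` holding `stratum_var = stratum`.
#' @param data Data frame supplying typical values for any covariate terms
#'   in the model (first row used; irrelevant for exposure-only models).
#' @param conf_level Confidence level.
#' @return An `irr_table` data frame with stratum, contrast, aIRR, CI
#'   bounds, and the SE of the log IRR.
#' @export
irr_contrasts <- function(fit, contrasts = default_contrasts(), data = NULL,
                          conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  base <- .typical_row(fit, data)
  rows <- lapply(contrasts, function(ct) {
    cv <- .contrast_vector(fit, ct, base)
    est <- sum(cv * fit$beta)
    se <- sqrt(drop(t(cv) %*% fit$vcov_robust %*% cv))
    data.frame(stratum = paste0(ct$stratum_var, "=", ct$stratum),
               contrast = paste0(ct$var, ": ", ct$a, " vs ", ct$b),
               log_irr = est, se_log_irr = se,
               aIRR = exp(est),
               ci_low = exp(est - z * se), ci_high = exp(est + z * se),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("irr_table", class(out))
  out
}

## a reference covariate row: first level of each factor, first non-missing
## value from `data` for remaining model variables
.typical_row <- function(fit, data = NULL) {
  row <- list()
  for (v in names(fit$xlevels)) row[[v]] <- fit$xlevels[[v]][1L]
  if (!is.null(data)) {
    needed <- setdiff(all.vars(stats::delete.response(fit$terms)), names(row))
    for (v in needed) row[[v]] <- data[[v]][which(!is.na(data[[v]]))[1L]]
  }
  row
}

## coefficient-space vector c such that c'beta is the contrast's log IRR
.contrast_vector <- function(fit, ct, base) {
  for (lev in c(ct$a, ct$b)) {
    if (!lev %in% fit$xlevels[[ct$var]]) {
      stop("unknown level '", lev, "' for factor ", ct$var)
    }
  }
  if (!ct$stratum %in% fit$xlevels[[ct$stratum_var]]) {
    stop("unknown level '", ct$stratum, "' for factor ", ct$stratum_var)
  }
  ra <- base; ra[[ct$stratum_var]] <- ct$stratum; ra[[ct$var]] <- ct$a
  rb <- base; rb[[ct$stratum_var]] <- ct$stratum; rb[[ct$var]] <- ct$b
  .cell_row(fit, as.data.frame(ra, stringsAsFactors = FALSE)) -
    .cell_row(fit, as.data.frame(rb, stringsAsFactors = FALSE))
}

#' Contrast vectors in coefficient space
#'
#' Builds the matrix whose columns are the coefficient-space vectors `c`
#' with `c'beta` equal to each requested within-stratum log IRR. Useful as
#' a low-dimensional auxiliary projection for raking (calibrating to the
#' influence functions of the target contrasts instead of every
#' coefficient).
#'
#' @inheritParams irr_contrasts
#' @return A numeric matrix, one column per contrast, rows aligned with
#'   `fit$beta`.
#' @export
contrast_matrix <- function(fit, contrasts = default_contrasts(), data = NULL) {
  base <- .typical_row(fit, data)
  cm <- vapply(contrasts, function(ct) as.numeric(.contrast_vector(fit, ct, base)),
               numeric(length(fit$beta)))
  cm <- matrix(cm, nrow = length(fit$beta),
               dimnames = list(names(fit$beta), names(contrasts)))
  cm
}

#' Default contrast set mirroring the headline comparisons
#'
#' Efavirenz vs nevirapine within implant users and within DMPA users, and
#' DMPA vs implant within efavirenz users.
#'
#' @return A list of contrast specifications for [irr_contrasts()].
#' @export
default_contrasts <- function() {
  list(
    implant_efv_vs_nvp = list(stratum_var = "contraceptive", stratum = "IMPLANT",
                              var = "art", a = "EFV", b = "NVP"),
    dmpa_efv_vs_nvp = list(stratum_var = "contraceptive", stratum = "DMPA",
                           var = "art", a = "EFV", b = "NVP"),
    efv_dmpa_vs_implant = list(stratum_var = "art", stratum = "EFV",
                               var = "contraceptive", a = "DMPA", b = "IMPLANT")
  )
}
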