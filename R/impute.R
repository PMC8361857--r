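## Multiple imputation by chained equations, with predictive-mean matching
## for continuous variables and multinomial draws for categorical ones.

## proper PMM: Bayesian draw of the regression coefficients, then donor
## matching on the predicted values (k nearest observed predictions)
.pmm_draw <- function(y_obs, X_obs, X_mis, k = 5L) {
  qx <- qr(X_obs)
  keep <- qx$pivot[seq_len(qx$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  n <- nrow(X_obs); p <- ncol(X_obs)
  fit <- stats::lm.fit(X_obs, y_obs)
  beta <- fit$coefficients
  res <- fit$residuals
  sigma2 <- sum(res^2) / stats::rchisq(1, max(n - p, 1))
  XtX_inv <- chol2inv(chol(crossprod(X_obs) + diag(1e-8, p)))
  beta_star <- beta + drop(chol(sigma2 * XtX_inv) %*% stats::rnorm(p))
  pred_obs <- drop(X_obs %*% beta)
  pred_mis <- drop(X_mis %*% beta_star)
  ## k-nearest-donor matching on predictions
  o <- order(pred_obs)
  po <- pred_obs[o]
  pos <- findInterval(pred_mis, po)
  n_obs <- length(po)
  vapply(seq_along(pred_mis), function(i) {
    lo <- max(1L, pos[i] - k); hi <- min(n_obs, pos[i] + k)
    cand <- lo:hi
    dd <- abs(po[cand] - pred_mis[i])
    cand <- cand[order(dd)][seq_len(min(k, length(cand)))]
    y_obs[o[sample(cand, 1L)]]
  }, y_obs[1L])
}

## one categorical imputation via multinomial (or binomial) regression
.cat_draw <- function(y_obs, X_obs, X_mis) {
  lev <- sort(unique(as.character(y_obs)))
  if (length(lev) == 1L) return(rep(lev, nrow(X_mis)))
  if (length(lev) == 2L) {
    df_o <- data.frame(.y = as.integer(as.character(y_obs) == lev[2L]), X_obs)
    fit <- suppressWarnings(stats::glm(.y ~ . - 1, data = df_o,
                                       family = stats::binomial()))
    p <- stats::predict(fit, newdata = data.frame(X_mis), type = "response")
    return(ifelse(stats::runif(length(p)) < p, lev[2L], lev[1L]))
  }
  df_o <- data.frame(.y = factor(y_obs, levels = lev), X_obs)
  fit <- nnet::multinom(.y ~ . - 1, data = df_o, trace = FALSE, maxit = 50)
  p <- stats::predict(fit, newdata = data.frame(X_mis), type = "probs")
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  apply(p, 1L, function(pr) sample(lev, 1L, prob = pr))
}

#' Multiple imputation by chained equations
#'
#' Cycles over the incomplete variables, imputing each from the others:
#' continuous variables by predictive-mean matching (5 donors, proper
#' Bayesian parameter draws), categorical variables by multinomial (or
#' logistic) regression draws. Predictors always include the exposure
#' categories (contraceptive method, ART regimen), the pregnancy indicator,
#' the other covariates, and - for time-varying variables - the preceding
#' and next non-missing values of the variable itself within the woman.
#' Each of the `m` completed datasets comes from an independent chain with
#' `burnin` cycles.
#'
#' @param periods Periods data frame; missingness must be confined to the
#'   covariate columns.
#' @param vars Variables to impute (default: every covariate column with
#'   missing values).
#' @param m Number of completed datasets (>= 2 for pooling).
#' @param burnin Chained-equation cycles per chain.
#' @param k Number of donors for predictive-mean matching.
#' @param seed Integer seed; imputation is deterministic given the seed.
#' @return A list of `m` completed data frames, of class `mi_set`.
#' @export
impute_chained <- function(periods, vars = NULL, m = 10L, burnin = 10L,
                           k = 5L, seed = 1L) {
  if (inherits(periods, "coded_cohort")) periods <- periods$periods
  cand <- intersect(.covariate_cols, names(periods))
  if (is.null(vars)) {
    vars <- cand[vapply(periods[cand], anyNA, logical(1))]
  }
  if (length(vars) == 0L) {
    out <- replicate(m, periods, simplify = FALSE)
    class(out) <- "mi_set"
    return(out)
  }
  for (v in vars) {
    if (all(is.na(periods[[v]]))) stop("cannot impute '", v, "': 100% missing")
  }
  set.seed(seed)

  ## fixed predictor frame: exposures, outcome, complete covariates, and
  ## within-woman neighbours of each incomplete variable
  base_pred <- data.frame(
    contraceptive = factor(periods$contraceptive),
    art = factor(periods$art),
    pregnancy = periods$pregnancy,
    log_time = log(periods$exposure_time)
  )
  for (v in setdiff(cand, vars)) {
    if (!anyNA(periods[[v]])) base_pred[[paste0("cov_", v)]] <- periods[[v]]
  }
  ## preceding / next non-missing values within woman (time order)
  o <- order(periods$woman_id, as.numeric(periods$start_date))
  neighbours <- list()
  for (v in vars) {
    x <- periods[[v]][o]
    wid <- periods$woman_id[o]
    locf <- function(z, id) {
      idx <- seq_along(z)
      idx[is.na(z)] <- NA
      filled <- idx
      for (i in seq_along(z)[-1L]) {
        if (is.na(filled[i]) && id[i] == id[i - 1L]) filled[i] <- filled[i - 1L]
      }
      z[filled]
    }
    prev_v <- locf(x, wid)
    next_v <- rev(locf(rev(x), rev(wid)))
    fill <- function(z) {
      if (is.numeric(z)) { z[is.na(z)] <- stats::median(z, na.rm = TRUE); z }
      else {
        tb <- table(z)
        z[is.na(z)] <- names(tb)[which.max(tb)]
        z
      }
    }
    nb <- data.frame(prev = fill(prev_v), nxt = fill(next_v))
    nb <- nb[order(o), , drop = FALSE]  # back to original row order
    names(nb) <- paste0(v, c("_prev", "_next"))
    neighbours[[v]] <- nb
  }

  miss_idx <- lapply(periods[vars], function(x) which(is.na(x)))
  obs_idx <- lapply(periods[vars], function(x) which(!is.na(x)))

  ## with a single incomplete variable the predictors are fully observed, so
  ## every cycle redraws from the same conditional: one cycle is exact, and
  ## the design matrix can be shared across chains
  single <- length(vars) == 1L
  n_cycles <- if (single) 1L else burnin
  X_single <- if (single) {
    stats::model.matrix(~ ., cbind(base_pred, neighbours[[vars]]))
  }

  one_chain <- function() {
    comp <- periods
    ## initialize missings from the observed margins
    for (v in vars) {
      mi <- miss_idx[[v]]
      comp[[v]][mi] <- sample(comp[[v]][obs_idx[[v]]], length(mi), replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (v in vars) {
        mi <- miss_idx[[v]]
        oi <- obs_idx[[v]]
        X <- if (single) X_single else {
          pred <- base_pred
          for (u in setdiff(vars, v)) pred[[paste0("cur_", u)]] <- comp[[u]]
          pred <- cbind(pred, neighbours[[v]])
          stats::model.matrix(~ ., pred)
        }
        if (is.numeric(periods[[v]])) {
          comp[[v]][mi] <- .pmm_draw(comp[[v]][oi], X[oi, , drop = FALSE],
                                     X[mi, , drop = FALSE], k = k)
        } else {
          comp[[v]][mi] <- .cat_draw(comp[[v]][oi], X[oi, , drop = FALSE],
                                     X[mi, , drop = FALSE])
        }
      }
    }
    comp
  }
  out <- lapply(seq_len(m), function(i) one_chain())
  class(out) <- "mi_set"
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled coefficients are the mean across fits; the total variance is the
#' within-imputation mean covariance plus `(1 + 1/m)` times the
#' between-imputation covariance. For rate-ratio tables the pooling is
#' done on the log scale and then exponentiated.
#'
#' @param fits A list of `poisson_fit` objects (common parameterization)
#'   or of `irr_table`s from [irr_contrasts()].
#' @return For fits: a `pooled_fit` usable by [irr_contrasts()]; for IRR
#'   tables: a pooled `irr_table`.
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1L)
  m <- length(fits)
  if (inherits(fits[[1L]], "irr_table")) {
    est <- sapply(fits, function(f) f$log_irr)
    v <- sapply(fits, function(f) f$se_log_irr^2)
    if (is.null(dim(est))) { est <- matrix(est, nrow = 1L); v <- matrix(v, nrow = 1L) }
    qbar <- rowMeans(est)
    within <- rowMeans(v)
    between <- apply(est, 1L, stats::var)
    if (m == 1L) between <- 0
    total <- within + (1 + 1 / m) * between
    out <- fits[[1L]]
    out$log_irr <- qbar
    out$se_log_irr <- sqrt(total)
    out$aIRR <- exp(qbar)
    out$ci_low <- exp(qbar - 1.96 * sqrt(total))
    out$ci_high <- exp(qbar + 1.96 * sqrt(total))
    return(out)
  }
  nm <- names(fits[[1L]]$beta)
  for (f in fits) {
    if (!identical(names(f$beta), nm)) stop("fits have mismatched parameterizations")
  }
  betas <- sapply(fits, `[[`, "beta")
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1L, dimnames = list(nm))
  qbar <- rowMeans(betas)
  within <- Reduce(`+`, lapply(fits, `[[`, "vcov_robust")) / m
  if (m > 1L) {
    dev <- betas - qbar
    between <- tcrossprod(dev) / (m - 1L)
  } else {
    between <- 0 * within
  }
  total <- within + (1 + 1 / m) * between
  pooled <- fits[[1L]]
  pooled$beta <- qbar
  pooled$vcov_robust <- total
  pooled$m <- m
  ## pooled per-woman influence: mean across imputations (used as the
  ## raking auxiliary when the naive model was imputed)
  if (!is.null(fits[[1L]]$influence)) {
    pooled$influence <- Reduce(`+`, lapply(fits, `[[`, "influence")) / m
  }
  class(pooled) <- c("pooled_fit", "poisson_fit")
  pooled
}
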