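## Generalized raking (calibration) of inverse-probability weights.

#' Calibrate design weights by generalized raking
#'
#' Finds calibrated weights `w_i = d_i * g(eta' h_i)` for the sampled units
#' such that the weighted sample totals of the auxiliary vectors match
#' their full-cohort totals, `sum_sampled w_i h_i = sum_full h_i`. The
#' default distance is exponential (classical raking, `g = exp`, keeping
#' weights positive), solved by Newton iteration with step-halving; on
#' non-convergence the linear (GREG) distance `g(u) = 1 + u` is used as a
#' fallback. Collinear auxiliary components are dropped with a warning.
#'
#' In the validation-sampling workflow the auxiliaries are the per-woman
#' influence functions from the Poisson model fit to the full error-prone
#' cohort, augmented with a constant column so the calibrated weights sum
#' to the cohort size; calibrating on influence functions is what makes the
#' weighted estimator efficient.
#'
#' @param d Base design weights of the sampled units (e.g. `1/p1`).
#' @param h_sample Matrix of auxiliary vectors for the sampled units (rows
#'   align with `d`).
#' @param totals Full-cohort column totals of the auxiliaries.
#' @param distance `"exponential"` or `"linear"`.
#' @param tol Convergence tolerance on the scaled calibration residual.
#' @param maxit Maximum Newton iterations.
#' @param fallback Try the linear distance if the exponential does not
#'   converge?
#' @return An object of class `raking_result`: list with `weights`,
#'   `base_weights`, `eta`, `iterations`, `calibration_residual` (max
#'   absolute component of the unmet constraint), `distance`, `converged`,
#'   and `kept` (indices of retained auxiliary components).
#' @export
raking_calibrate <- function(d, h_sample, totals,
                             distance = c("exponential", "linear"),
                             tol = 1e-8, maxit = 50L, fallback = TRUE) {
  distance <- match.arg(distance)
  h_sample <- as.matrix(h_sample)
  stopifnot(length(d) == nrow(h_sample), length(totals) == ncol(h_sample),
            all(d > 0), all(is.finite(totals)))

  ## drop collinear auxiliary components
  qr_h <- qr(h_sample * sqrt(d))
  kept <- sort(qr_h$pivot[seq_len(qr_h$rank)])
  if (length(kept) < ncol(h_sample)) {
    warning("dropping ", ncol(h_sample) - length(kept),
            " collinear auxiliary component(s)")
  }
  h <- h_sample[, kept, drop = FALSE]
  tot <- totals[kept]
  scale <- 1 + abs(tot)

  resid_full <- function(w) {
    drop(crossprod(h_sample, w)) - totals
  }

  solve_newton <- function(gfun, gprime) {
    eta <- numeric(ncol(h))
    f_old <- Inf
    for (it in 0:maxit) {
      u <- pmin(drop(h %*% eta), 500)
      w <- d * gfun(u)
      f <- drop(crossprod(h, w)) - tot
      if (max(abs(f) / scale) < tol) {
        return(list(eta = eta, w = w, iterations = it, converged = TRUE))
      }
      if (it == maxit) break
      J <- crossprod(h, h * (d * gprime(u)))
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) break
      ## step-halving on the residual norm
      sz <- 1
      repeat {
        eta_new <- eta - sz * step
        u_new <- pmin(drop(h %*% eta_new), 500)
        f_new <- drop(crossprod(h, d * gfun(u_new))) - tot
        if (max(abs(f_new) / scale) < max(abs(f) / scale) || sz < 1e-6) break
        sz <- sz / 2
      }
      eta <- eta_new
      f_old <- max(abs(f) / scale)
    }
    u <- pmin(drop(h %*% eta), 500)
    list(eta = eta, w = d * gfun(u), iterations = maxit, converged = FALSE)
  }

  result <- NULL
  used <- distance
  if (distance == "exponential") {
    result <- solve_newton(exp, exp)
    if (!result$converged && fallback) {
      warning("exponential raking did not converge; falling back to the ",
              "linear (GREG) distance")
      used <- "linear"
    }
  }
  if (used == "linear") {
    lin <- solve_newton(function(u) 1 + u, function(u) rep(1, length(u)))
    if (is.null(result) || lin$converged || !result$converged) result <- lin
  }
  res_vec <- resid_full(result$w)
  if (!result$converged) {
    stop("raking failed to converge under the ", used, " distance; ",
         "max calibration residual ", format(max(abs(res_vec))))
  }
  if (any(result$w <= 0)) {
    stop("raking produced non-positive calibrated weights (", used,
         " distance); the sample cannot be calibrated to these totals")
  }
  structure(list(
    weights = result$w,
    base_weights = d,
    eta = result$eta,
    iterations = result$iterations,
    calibration_residual = max(abs(res_vec)),
    distance = used,
    converged = result$converged,
    kept = kept
  ), class = "raking_result")
}

#' @export
print.raking_result <- function(x, ...) {
  cat("Generalized raking (", x$distance, "): ", length(x$weights),
      " units, ", x$iterations, " iterations, max residual ",
      format(x$calibration_residual, digits = 3), "\n", sep = "")
  invisible(x)
}
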