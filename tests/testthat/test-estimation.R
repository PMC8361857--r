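# helper: a small two-cell rate dataset with known crude rates
two_cell <- function() {
  data.frame(
    woman_id = sprintf("w%03d", 1:90),
    pregnancy = c(rep(1L, 5), rep(0L, 45), rep(1L, 8), rep(0L, 32)),
    art = factor(rep(c("NVP", "EFV"), c(50, 40)), levels = c("NVP", "EFV")),
    exposure_time = 1,
    stringsAsFactors = FALSE
  )
}

test_that("intercept-only fit recovers the closed-form Poisson MLE", {
  d <- data.frame(woman_id = as.character(1:10),
                  pregnancy = c(rep(1L, 5), rep(0L, 5)),
                  exposure_time = 10)
  fit <- fit_poisson_robust(d, pregnancy ~ 1)
  expect_equal(unname(fit$beta), log(5 / 100), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("two-cell fit equals the crude rate ratio; weights of 1 are a no-op", {
  d <- two_cell()
  fit <- fit_poisson_robust(d, pregnancy ~ art)
  # rates 5/50 vs 8/40 -> log IRR = log 2
  expect_equal(unname(fit$beta["artEFV"]), log(2), tolerance = 1e-8)
  fit_w <- fit_poisson_robust(d, pregnancy ~ art, weights = rep(1, nrow(d)))
  expect_equal(fit_w$beta, fit$beta, tolerance = 1e-10)
  expect_equal(fit_w$vcov_robust, fit$vcov_robust, tolerance = 1e-10)
})

test_that("fit matches glm and sandwich::vcovCL oracles", {
  skip_if_not_installed("sandwich")
  cfg <- identity_config(n_women = 800, seed = 71)
  s <- generate_cohort(cfg, phases = "emr")
  pp <- prepare_periods(suppressWarnings(
    code_cohort(s$emr_visits, study_end = cfg$study_end,
                lookahead_days = cfg$lookahead_days)))
  fit <- fit_poisson_robust(pp, pregnancy ~ contraceptive * art)
  g <- stats::glm(pregnancy ~ contraceptive * art, data = pp,
                  family = stats::poisson(), offset = log(exposure_time))
  expect_equal(fit$beta, coef(g), tolerance = 1e-6)
  vc <- sandwich::vcovCL(g, cluster = pp$woman_id, type = "HC0", cadjust = FALSE)
  expect_equal(fit$vcov_robust, vc, tolerance = 1e-5, ignore_attr = TRUE)
  # score identity: influence sums to zero; vcov = crossprod(influence)
  expect_lt(max(abs(colSums(fit$influence))), 1e-6)
  expect_equal(crossprod(fit$influence), fit$vcov_robust,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(nrow(fit$influence), fit$n_clusters)
})

test_that("rank deficiency and missing model variables are named errors", {
  d <- two_cell()
  d$contraceptive <- factor("IMPLANT", levels = c("NONE", "IMPLANT", "DMPA"))
  expect_error(fit_poisson_robust(d, pregnancy ~ contraceptive + art),
               "rank deficient")
  d2 <- two_cell()
  d2$cd4 <- NA_real_
  expect_error(fit_poisson_robust(d2, pregnancy ~ art + cd4), "cd4")
})

test_that("prepare_periods drops excluded categories and sets references", {
  p <- data.frame(
    woman_id = as.character(1:5),
    contraceptive = c("NONE", "IMPLANT", "DMPA", "MISSING", "NONE"),
    art = c("NVP", "EFV", "NRTI_ONLY", "NVP", "COMBINATION"),
    pregnancy = 0L, exposure_time = 1, stringsAsFactors = FALSE)
  out <- prepare_periods(p)
  expect_equal(nrow(out), 2L)
  expect_identical(levels(out$contraceptive)[1], "NONE")
  expect_identical(levels(out$art)[1], "NVP")
  out2 <- prepare_periods(p, drop_art = "MISSING")
  expect_equal(nrow(out2), 4L)
})

test_that("raking leaves already-calibrated weights untouched", {
  # constant auxiliary with totals already met
  d <- rep(2, 5)
  h <- matrix(1, 5, 1)
  r <- raking_calibrate(d, h, totals = 10)
  expect_equal(r$weights, d)
  expect_equal(r$iterations, 0L)
  expect_lt(r$calibration_residual, 1e-8)

  # full sample with unit weights: nothing to do
  h2 <- cbind(1, c(3, 1, 4, 1, 5))
  r2 <- raking_calibrate(rep(1, 5), h2, totals = colSums(h2))
  expect_equal(r2$weights, rep(1, 5))
})

test_that("1-D raking matches the closed-form solution", {
  # w_i = d_i exp(eta h_i), solve sum w_i h_i = T with h in {1, 2}:
  # a e^eta + 2 b e^(2 eta) = T  with  a = sum_{h=1} d h, b = sum_{h=2} d
  d <- c(2, 2, 3, 1, 1, 1)
  h <- matrix(c(1, 1, 1, 2, 2, 2), ncol = 1)
  T_ <- 14
  a <- sum(d[h == 1]); b <- sum(d[h == 2])
  x <- (-a + sqrt(a^2 + 8 * b * T_)) / (4 * b)   # x = e^eta
  w_closed <- d * x^h[, 1]
  r <- raking_calibrate(d, h, totals = T_)
  expect_equal(unname(r$weights), unname(w_closed), tolerance = 1e-7)
  expect_lt(r$calibration_residual, 1e-6)
  expect_identical(r$distance, "exponential")
  expect_true(all(r$weights > 0))
})

test_that("collinear auxiliaries are dropped with a warning", {
  h <- cbind(1, c(1, 2, 3, 4), 2 * c(1, 2, 3, 4))
  expect_warning(r <- raking_calibrate(rep(1, 4), h, totals = colSums(h) + c(0, 1, 2)),
                 "collinear")
  expect_lt(r$calibration_residual, 1e-6)
})

test_that("irr_contrasts gives within-stratum ratios with exact CI arithmetic", {
  d <- two_cell()
  fit <- fit_poisson_robust(d, pregnancy ~ art)
  ct <- list(efv_vs_nvp = list(stratum_var = "art", stratum = "EFV",
                               var = "art", a = "EFV", b = "NVP"))
  # degenerate self-contrast: IRR exactly 1 with zero-width CI
  self <- irr_contrasts(fit, list(x = list(stratum_var = "art", stratum = "NVP",
                                           var = "art", a = "NVP", b = "NVP")))
  expect_equal(self$aIRR, 1)
  expect_equal(self$ci_low, 1)
  expect_equal(self$ci_high, 1)

  tab <- irr_contrasts(fit, ct)
  expect_equal(tab$log_irr, log(2), tolerance = 1e-8)
  z <- qnorm(0.975)
  expect_equal(tab$ci_low, exp(tab$log_irr - z * tab$se_log_irr))
  expect_equal(tab$ci_high, exp(tab$log_irr + z * tab$se_log_irr))
  expect_error(irr_contrasts(fit, list(x = list(stratum_var = "art", stratum = "EFV",
                                                var = "art", a = "XXX", b = "NVP"))),
               "unknown level")
  # arithmetic oracle: log IRR 0.693, SE 0.2 -> CI (1.35, 2.96)
  expect_equal(round(exp(log(2) - z * 0.2), 2), 1.35)
  expect_equal(round(exp(log(2) + z * 0.2), 2), 2.96)
})

test_that("interaction contrasts cancel covariate terms", {
  cfg <- identity_config(n_women = 800, seed = 81)
  s <- generate_cohort(cfg, phases = "emr")
  cc <- suppressWarnings(code_cohort(s$emr_visits, study_end = cfg$study_end,
                                     lookahead_days = cfg$lookahead_days))
  pp <- prepare_periods(cc)
  f <- pregnancy ~ contraceptive * art + avg_age + calendar_year
  fit <- fit_poisson_robust(pp, f)
  tab <- irr_contrasts(fit, default_contrasts()["implant_efv_vs_nvp"], data = pp)
  # the same contrast from raw coefficients (covariates drop out)
  b <- fit$beta
  expect_equal(tab$log_irr,
               unname(b["artEFV"] + b["contraceptiveIMPLANT:artEFV"]),
               tolerance = 1e-10)
})

test_that("Rubin pooling matches hand computations", {
  d <- two_cell()
  fit <- fit_poisson_robust(d, pregnancy ~ art)
  pooled <- pool_rubin(list(fit, fit, fit))
  expect_equal(pooled$beta, fit$beta)
  expect_equal(pooled$vcov_robust, fit$vcov_robust, tolerance = 1e-12)

  # m = 2 with estimates (0, 2), within-variance 1 each:
  # pooled 1, total = 1 + 1.5 * 2 = 4
  t1 <- data.frame(stratum = "s", contrast = "c", log_irr = 0, se_log_irr = 1,
                   aIRR = 1, ci_low = NA, ci_high = NA)
  class(t1) <- c("irr_table", class(t1))
  t2 <- t1; t2$log_irr <- 2
  pl <- pool_rubin(list(t1, t2))
  expect_equal(pl$log_irr, 1)
  expect_equal(pl$se_log_irr, 2)
  expect_equal(pl$aIRR, exp(1))

  fitb <- fit_poisson_robust(d, pregnancy ~ 1)
  expect_error(pool_rubin(list(fit, fitb)), "parameterizations")
})

test_that("imputation is deterministic, trivial when complete, and errors on all-NA", {
  cfg <- identity_config(n_women = 200, seed = 91)
  s <- generate_cohort(cfg, phases = "emr")
  cc <- suppressWarnings(code_cohort(s$emr_visits, study_end = cfg$study_end,
                                     lookahead_days = cfg$lookahead_days))
  pp <- prepare_periods(cc)

  # identity config leaves no missing covariates: m identical copies
  imps <- impute_chained(pp, m = 3, seed = 7)
  expect_length(imps, 3L)
  expect_identical(imps[[1]], pp)
  expect_identical(imps[[2]], pp)

  # mask cd4 and impute
  set.seed(1)
  holes <- sample(nrow(pp), floor(0.25 * nrow(pp)))
  pm <- pp
  pm$cd4[holes] <- NA
  i1 <- impute_chained(pm, m = 2, burnin = 3, seed = 5)
  i2 <- impute_chained(pm, m = 2, burnin = 3, seed = 5)
  expect_identical(i1, i2)
  expect_false(anyNA(i1[[1]]$cd4))
  # imputed values are observed donors (PMM draws real values)
  expect_true(all(i1[[1]]$cd4[holes] %in% pp$cd4[-holes] | FALSE))
  # pooled mean within 3 SE of the pre-masking mean
  pooled_mean <- mean(sapply(i1, function(d) mean(d$cd4)))
  se <- sd(pp$cd4) / sqrt(nrow(pp))
  expect_lt(abs(pooled_mean - mean(pp$cd4)), 3 * se)

  pa <- pm
  pa$cd4 <- NA_real_
  expect_error(impute_chained(pa, m = 2), "100% missing")
})

test_that("categorical imputation draws valid levels", {
  cfg <- identity_config(n_women = 150, seed = 101)
  s <- generate_cohort(cfg, phases = "emr")
  cc <- suppressWarnings(code_cohort(s$emr_visits, study_end = cfg$study_end,
                                     lookahead_days = cfg$lookahead_days))
  pp <- prepare_periods(cc)
  set.seed(2)
  holes <- sample(nrow(pp), floor(0.2 * nrow(pp)))
  pm <- pp
  pm$marital[holes] <- NA
  im <- impute_chained(pm, m = 2, burnin = 3, seed = 9)
  expect_false(anyNA(im[[1]]$marital))
  expect_true(all(im[[1]]$marital[holes] %in% unique(pp$marital)))
})
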