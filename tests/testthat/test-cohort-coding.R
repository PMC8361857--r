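test_that("contraceptive hierarchy resolves label sets", {
  expect_identical(assign_contraceptive_category(c("implant_lng", "condom")), "IMPLANT")
  expect_identical(assign_contraceptive_category(c("iud", "implant_etg", "dmpa")), "MEC")
  expect_identical(assign_contraceptive_category(character(0)), "NONE")
  expect_identical(assign_contraceptive_category("dmpa;ocp"), "DMPA")
  expect_identical(assign_contraceptive_category(NA), "MISSING")
  expect_warning(res <- assign_contraceptive_category("galaxy_brain"),
                 "unrecognized")
  expect_identical(res, "MISSING")
})

test_that("hierarchy is idempotent under lower-priority additions", {
  base <- c("implant_lng")
  for (lower in c("dmpa", "ocp", "condom", "natural", "none")) {
    expect_identical(assign_contraceptive_category(c(base, lower)), "IMPLANT")
  }
  expect_identical(assign_contraceptive_category(c("iud", "implant_lng", "ocp")), "MEC")
})

test_that("ART categorization follows the three-drug rule", {
  expect_identical(assign_art_category(c("efavirenz", "tenofovir", "lamivudine")), "EFV")
  expect_identical(assign_art_category(c("nevirapine", "zidovudine", "lamivudine")), "NVP")
  expect_identical(assign_art_category(c("lopinavir_r", "tenofovir", "lamivudine")), "PI")
  expect_identical(
    assign_art_category(c("efavirenz", "lopinavir_r", "tenofovir", "lamivudine")),
    "COMBINATION")
  expect_identical(assign_art_category(character(0)), "NO_ART")
  expect_identical(assign_art_category(""), "NO_ART")
  # one or two drugs are not assumed untreated
  expect_identical(assign_art_category(c("tenofovir", "lamivudine")), "MISSING")
  expect_identical(assign_art_category(c("tenofovir", "lamivudine", "zidovudine")),
                   "NRTI_ONLY")
  expect_identical(assign_art_category(NA), "MISSING")
})

test_that("vectorized coders agree with the scalar rules", {
  x <- c("implant_lng;condom", "iud;implant_etg;dmpa", "", "dmpa", NA, "ocp;condom")
  expect_identical(code_contraceptive_vec(x),
                   c("IMPLANT", "MEC", "NONE", "DMPA", "MISSING", "OCP"))
  a <- c("efavirenz;tenofovir;lamivudine", "", NA, "tenofovir;lamivudine",
         "tenofovir;lamivudine;zidovudine",
         "efavirenz;nevirapine;tenofovir;lamivudine")
  expect_identical(code_art_vec(a),
                   c("EFV", "NO_ART", "MISSING", "MISSING", "NRTI_ONLY", "COMBINATION"))
})

test_that("conception dating follows LMP > gestational age > EDD", {
  # definitional offsets
  expect_equal(estimate_conception_date(lmp_date = as.Date("2013-01-01"),
                                        report_date = as.Date("2013-03-01")),
               as.Date("2013-01-15"))
  expect_equal(estimate_conception_date(edd_date = as.Date("2013-10-08"),
                                        report_date = as.Date("2013-03-01")),
               as.Date("2013-01-15"))
  expect_equal(estimate_conception_date(gest_age_weeks = 8,
                                        report_date = as.Date("2013-03-12")),
               as.Date("2013-01-29"))
  # precedence: LMP wins over both, gestational age over EDD
  expect_equal(estimate_conception_date(lmp_date = as.Date("2013-01-01"),
                                        gest_age_weeks = 20,
                                        edd_date = as.Date("2013-10-20"),
                                        report_date = as.Date("2013-06-01")),
               as.Date("2013-01-15"))
  expect_equal(estimate_conception_date(gest_age_weeks = 8,
                                        edd_date = as.Date("2013-12-01"),
                                        report_date = as.Date("2013-03-12")),
               as.Date("2013-01-29"))
  # capped at the report date
  expect_equal(estimate_conception_date(lmp_date = as.Date("2013-03-10"),
                                        report_date = as.Date("2013-03-12")),
               as.Date("2013-03-12"))
  expect_error(estimate_conception_date(report_date = as.Date("2013-03-12"),
                                        woman_id = "w9"),
               "w9")
  expect_warning(
    estimate_conception_date(lmp_date = as.Date("2013-01-01"),
                             edd_date = as.Date("2014-06-01"),
                             report_date = as.Date("2013-06-01")),
    "diverge")
})

EFV <- "efavirenz;tenofovir;lamivudine"
NVP <- "nevirapine;zidovudine;lamivudine"

test_that("worked timeline: exposure switch then pregnancy then resumption", {
  v <- mk_visits("F1", c(0, 400, 800),
                 contraceptive = "implant_lng",
                 art = c(NVP, EFV, EFV),
                 preg_reported = c(FALSE, FALSE, TRUE),
                 lmp_day = c(NA, NA, 486))
  p <- segment_periods(v, study_end = D0 + 800)
  expect_equal(nrow(p), 3L)
  expect_equal(as.numeric(p$start_date - D0), c(0, 400, 766))
  expect_equal(as.numeric(p$end_date - D0), c(400, 500, 800))
  expect_identical(p$contraceptive, rep("IMPLANT", 3))
  expect_identical(p$art, c("NVP", "EFV", "EFV"))
  expect_equal(p$pregnancy, c(0L, 1L, 0L))
  expect_equal(p$conception_date[2], D0 + 500)
  expect_equal(p$exposure_time, c(400, 100, 34) / 365.25)
  # person-time conservation: exposure + censored window = full span
  expect_equal(sum(p$exposure_time) * 365.25 + 266, 800)
})

test_that("trivial timelines: no-change pair and single visit", {
  v <- mk_visits("F2", c(0, 300), contraceptive = "dmpa", art = NVP)
  p <- segment_periods(v, study_end = D0 + 300)
  expect_equal(nrow(p), 1L)
  expect_equal(p$exposure_time, 300 / 365.25)
  expect_identical(p$contraceptive, "DMPA")
  expect_equal(p$pregnancy, 0L)

  v1 <- mk_visits("F3", 0)
  expect_equal(nrow(segment_periods(v1, study_end = D0 + 300)), 0L)
})

test_that("periods split where the coded category changes", {
  v <- mk_visits("F4", c(0, 100, 300),
                 contraceptive = c("implant_lng;condom", "iud;implant_etg;dmpa",
                                   "iud;implant_etg;dmpa"))
  p <- segment_periods(v, study_end = D0 + 300)
  expect_equal(nrow(p), 2L)
  expect_identical(p$contraceptive, c("IMPLANT", "MEC"))
  expect_equal(as.numeric(p$start_date - D0), c(0, 100))
  expect_equal(as.numeric(p$end_date - D0), c(100, 300))
})

test_that("each dating source places the conception correctly", {
  # LMP: conception at day 134, window extends past observation end
  v5 <- mk_visits("F5", c(0, 200, 250),
                  preg_reported = c(FALSE, TRUE, FALSE),
                  lmp_day = c(NA, 120, NA))
  p5 <- segment_periods(v5, study_end = D0 + 250)
  expect_equal(nrow(p5), 1L)
  expect_equal(as.numeric(p5$end_date - D0), 134)
  expect_equal(p5$pregnancy, 1L)

  # EDD: conception 400 - 266 = 134, risk resumes at 400
  v6 <- mk_visits("F6", c(0, 300, 500),
                  preg_reported = c(FALSE, TRUE, FALSE),
                  edd_day = c(NA, 400, NA))
  p6 <- segment_periods(v6, study_end = D0 + 500)
  expect_equal(as.numeric(p6$start_date - D0), c(0, 400))
  expect_equal(as.numeric(p6$end_date - D0), c(134, 500))
  expect_equal(p6$pregnancy, c(1L, 0L))

  # gestational age: 8 weeks at day 70 -> conception day 28
  v7 <- mk_visits("F7", c(0, 70, 200),
                  preg_reported = c(FALSE, TRUE, FALSE),
                  gest_age_weeks = c(NA, 8, NA))
  p7 <- segment_periods(v7, study_end = D0 + 200)
  expect_equal(nrow(p7), 1L)
  expect_equal(as.numeric(p7$end_date - D0), 28)
  expect_equal(p7$pregnancy, 1L)
})

test_that("a woman can contribute multiple pregnancies", {
  v <- mk_visits("F8", c(0, 300, 700, 1200),
                 preg_reported = c(FALSE, TRUE, TRUE, FALSE),
                 lmp_day = c(NA, 86, 486, NA))
  p <- segment_periods(v, study_end = D0 + 1200)
  expect_equal(as.numeric(p$start_date - D0), c(0, 366, 766))
  expect_equal(as.numeric(p$end_date - D0), c(100, 500, 1200))
  expect_equal(p$pregnancy, c(1L, 1L, 0L))
  # person-time conservation with two full censored windows
  expect_equal(sum(p$exposure_time) * 365.25 + 2 * 266, 1200)
})

test_that("OUTCOME_RECORDS resumes risk at the recorded outcome date", {
  v <- mk_visits("F9", c(0, 300, 400),
                 preg_reported = c(FALSE, TRUE, FALSE),
                 lmp_day = c(NA, 86, NA),
                 outcome_day = c(NA, 180, NA))
  fixed <- segment_periods(v, study_end = D0 + 400)
  expect_equal(as.numeric(fixed$start_date - D0), c(0, 366))
  outc <- segment_periods(v, censor_rule = "OUTCOME_RECORDS", study_end = D0 + 400)
  expect_equal(as.numeric(outc$start_date - D0), c(0, 180))
  expect_equal(as.numeric(outc$end_date - D0), c(100, 400))
})

test_that("conceptions dated before the first visit are dropped with a warning", {
  v <- mk_visits("F10", c(50, 100, 300),
                 preg_reported = c(FALSE, TRUE, FALSE),
                 lmp_day = c(NA, 0, NA))
  expect_warning(p <- segment_periods(v, study_end = D0 + 300), "before first visit")
  expect_equal(nrow(p), 1L)
  expect_equal(p$pregnancy, 0L)
  expect_equal(as.numeric(p$start_date - D0), 50)
})

test_that("pregnancies reported after study end within the lookahead count", {
  v <- mk_visits("F11", c(0, 250, 400),
                 preg_reported = c(FALSE, FALSE, TRUE),
                 lmp_day = c(NA, NA, 216))
  p <- segment_periods(v, study_end = D0 + 300, lookahead_days = 270L)
  expect_equal(nrow(p), 1L)
  expect_equal(as.numeric(p$end_date - D0), 230)
  expect_equal(p$pregnancy, 1L)
  # beyond the lookahead the report is not scanned
  p2 <- segment_periods(v, study_end = D0 + 300, lookahead_days = 50L)
  expect_equal(p2$pregnancy, 0L)
  expect_equal(as.numeric(p2$end_date - D0), 250)
})

test_that("repeat reports of the same pregnancy are deduplicated", {
  v <- mk_visits("F12", c(0, 300, 350, 500),
                 preg_reported = c(FALSE, TRUE, TRUE, FALSE),
                 lmp_day = c(NA, 86, NA, NA),
                 gest_age_weeks = c(NA, NA, 35, NA))
  p <- segment_periods(v, study_end = D0 + 500)
  expect_equal(sum(p$pregnancy), 1L)
  expect_equal(as.numeric(p$end_date - D0), c(100, 500))
})

test_that("exposure categories flow through segmentation", {
  v <- mk_visits("F13", c(0, 200, 400),
                 art = c("tenofovir;lamivudine",
                         "tenofovir;lamivudine;zidovudine",
                         "tenofovir;lamivudine;zidovudine"))
  p <- segment_periods(v, study_end = D0 + 400)
  expect_identical(p$art, c("MISSING", "NRTI_ONLY"))
})

test_that("segmentation is deterministic and rejects unsorted input", {
  v <- mk_visits("F1", c(0, 400, 800), contraceptive = "implant_lng",
                 art = c(NVP, EFV, EFV),
                 preg_reported = c(FALSE, FALSE, TRUE),
                 lmp_day = c(NA, NA, 486))
  expect_identical(segment_periods(v, study_end = D0 + 800),
                   segment_periods(v, study_end = D0 + 800))
  expect_error(segment_periods(v[c(2, 1, 3), ], study_end = D0 + 800), "sorted")
})

test_that("covariate snapshots come from the nearest visit at or before start", {
  v <- mk_visits("F14", c(0, 100, 300),
                 contraceptive = c("none", "dmpa", "dmpa"),
                 who_stage = c(1, 3, 3), cd4 = c(400, NA, 500),
                 age = c(30, 30 + 100 / 365.25, 30 + 300 / 365.25),
                 marital = "married", education = "some_primary",
                 n_children = 2, weight = 60, bmi = 22, anti_tb = FALSE,
                 program = "A")
  p <- segment_periods(v, study_end = D0 + 300)
  p <- attach_covariates(p, v)
  expect_equal(p$who_stage, c(1, 3))
  # missing covariates propagate as missing
  expect_equal(p$cd4, c(400, NA))
  # age advanced to the period midpoint
  expect_equal(p$avg_age, 30 + c(50, 200) / 365.25)
  expect_equal(p$calendar_year,
               1970 + (as.numeric(D0) + c(50, 200)) / 365.25)
})

test_that("code_cohort assembles multi-woman cohorts and conserves pregnancies", {
  v <- rbind(
    mk_visits("A", c(0, 400, 800), contraceptive = "implant_lng",
              art = c(NVP, EFV, EFV), preg_reported = c(FALSE, FALSE, TRUE),
              lmp_day = c(NA, NA, 486)),
    mk_visits("B", c(0, 300), contraceptive = "dmpa", art = NVP),
    mk_visits("C", 0)
  )
  cc <- code_cohort(v, study_end = D0 + 800)
  expect_s3_class(cc, "coded_cohort")
  expect_equal(cc$women_count, 2L)
  expect_equal(sum(cc$periods$pregnancy), 1L)
  expect_equal(cc$total_women_years, sum(cc$periods$exposure_time))
  expect_setequal(unique(cc$periods$woman_id), c("A", "B"))
  # equals per-woman segmentation
  pa <- segment_periods(v[v$woman_id == "A", ], study_end = D0 + 800)
  expect_equal(cc$periods[cc$periods$woman_id == "A",
                          names(pa)], pa, ignore_attr = TRUE)
})

test_that("visit and period tables round-trip through CSV", {
  v <- mk_visits("A", c(0, 400, 800), contraceptive = "implant_lng",
                 art = c(NVP, EFV, EFV), preg_reported = c(FALSE, FALSE, TRUE),
                 lmp_day = c(NA, NA, 486))
  f <- tempfile(fileext = ".csv")
  write_visits(v, f)
  v2 <- read_visits(f)
  expect_equal(v2$visit_date, v$visit_date)
  expect_equal(v2$lmp_date, v$lmp_date)

  p <- segment_periods(v, study_end = D0 + 800)
  f2 <- tempfile(fileext = ".csv")
  write_periods(p, f2)
  p2 <- read_periods(f2)
  expect_equal(p2$start_date, p$start_date)
  expect_equal(p2$exposure_time, p$exposure_time)
  expect_equal(p2$pregnancy, p$pregnancy)
  unlink(c(f, f2))
})
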