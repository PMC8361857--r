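## Cohort coding: visits -> observation periods.
##
## Conventions: half-open intervals [start, end) at day resolution;
## exposure time in years = days / 365.25; a new exposure value takes
## effect on its visit date.

DAYS_PER_YEAR <- 365.25
GESTATION_DAYS <- 266L   # 38 weeks from conception to term delivery
OVULATION_OFFSET <- 14L  # conception ~ LMP + 14 days

#' Estimate the date of likely conception from a pregnancy report
#'
#' Backdates a reported pregnancy to its likely conception date using, in
#' order of precedence, the last menstrual period (LMP + 14 days), the
#' estimated gestational age (report date - 7*weeks + 14 days), or the
#' expected date of delivery (EDD - 266 days). The returned date is capped
#' at the report date. All arguments are vectorized and recycled to a
#' common length.
#'
#' @param lmp_date,edd_date `Date` vectors (may be `NA`).
#' @param gest_age_weeks Numeric vector of gestational ages in weeks at the
#'   report date (may be `NA`).
#' @param report_date `Date` vector: the visit date at which the pregnancy
#'   was reported.
#' @param woman_id Optional identifiers used in error messages.
#' @return A `Date` vector of estimated conception dates.
#' @details When both LMP and EDD are recorded and their implied conception
#'   dates diverge by more than 30 days, a warning identifies the records;
#'   the LMP-based date is still used.
#' @export
estimate_conception_date <- function(lmp_date = NULL, gest_age_weeks = NULL,
                                     edd_date = NULL, report_date,
                                     woman_id = NULL) {
  n <- length(report_date)
  as_date_col <- function(x) {
    if (is.null(x)) return(rep(as.Date(NA), n))
    rep_len(as.Date(x), n)
  }
  lmp <- as_date_col(lmp_date)
  edd <- as_date_col(edd_date)
  ga  <- if (is.null(gest_age_weeks)) rep(NA_real_, n) else rep_len(as.numeric(gest_age_weeks), n)
  report_date <- as.Date(report_date)

  none <- is.na(lmp) & is.na(ga) & is.na(edd)
  if (any(none)) {
    who <- if (is.null(woman_id)) which(none) else woman_id[none]
    stop("conception dating unavailable (no LMP, gestational age, or EDD) for: ",
         paste(utils::head(who, 5L), collapse = ", "))
  }
  out <- edd - GESTATION_DAYS
  use_ga <- !is.na(ga)
  out[use_ga] <- report_date[use_ga] - round(ga[use_ga] * 7) + OVULATION_OFFSET
  use_lmp <- !is.na(lmp)
  out[use_lmp] <- lmp[use_lmp] + OVULATION_OFFSET

  both <- !is.na(lmp) & !is.na(edd)
  if (any(both)) {
    div <- abs(as.numeric((lmp + OVULATION_OFFSET) - (edd - GESTATION_DAYS)))[both]
    if (any(div > 30)) {
      who <- if (is.null(woman_id)) which(both)[div > 30] else woman_id[both][div > 30]
      warning("LMP- and EDD-based conception dates diverge by > 30 days for: ",
              paste(utils::head(who, 5L), collapse = ", "), "; using LMP")
    }
  }
  pmin(out, report_date)
}

## Deduplicate and order conception events for one woman; returns a list
## with conception dates and censoring-window ends. Repeated reports whose
## conception falls inside an earlier pregnancy's window are the same
## pregnancy.
.resolve_pregnancies <- function(conceptions, outcome_dates, censor_rule) {
  o <- order(conceptions)
  conceptions <- conceptions[o]
  outcome_dates <- outcome_dates[o]
  keep_c <- keep_w <- numeric(0)
  last_end <- -Inf
  for (k in seq_along(conceptions)) {
    ck <- as.numeric(conceptions[k])
    if (ck < last_end) next  # duplicate report of the current pregnancy
    wk <- if (censor_rule == "OUTCOME_RECORDS" && !is.na(outcome_dates[k])) {
      as.numeric(outcome_dates[k])
    } else {
      ck + GESTATION_DAYS
    }
    keep_c <- c(keep_c, ck)
    keep_w <- c(keep_w, wk)
    last_end <- wk
  }
  list(conception = keep_c, window_end = keep_w)
}

## Core single-woman segmentation on plain numeric-day vectors; returns a
## list of parallel column vectors, or NULL for women contributing no
## person-time. `conception_num` holds the precomputed conception day for
## each visit (NA where no dateable report).
.segment_one <- function(wid, vnum, cat_c, cat_a, conception_num, outcome_num,
                         censor_rule, end_num, lookahead_days) {
  in_window <- vnum <= end_num
  if (sum(in_window) < 2L) return(NULL)
  obs_start <- min(vnum[in_window])
  obs_end <- max(vnum[in_window])

  ## --- pregnancy events -------------------------------------------------
  scan <- which(!is.na(conception_num) & vnum <= end_num + lookahead_days)
  conceptions <- numeric(0); windows <- numeric(0)
  if (length(scan)) {
    cdn <- conception_num[scan]
    out_d <- outcome_num[scan]
    early <- cdn < obs_start
    if (any(early)) {
      warning("woman ", wid, ": ", sum(early),
              " conception(s) dated before first visit; dropped from risk sets")
    }
    keep <- !early & cdn > obs_start & cdn < obs_end
    preg <- .resolve_pregnancies(cdn[keep], out_d[keep], censor_rule)
    conceptions <- preg$conception
    windows <- preg$window_end
  }

  ## --- risk segments between pregnancies --------------------------------
  seg_start <- c(obs_start, windows)
  seg_end <- c(conceptions, obs_end)
  seg_preg <- c(rep(1L, length(conceptions)), 0L)
  seg_conc <- c(conceptions, NA_real_)
  ok <- seg_end > seg_start
  seg_start <- seg_start[ok]; seg_end <- seg_end[ok]
  seg_preg <- seg_preg[ok]; seg_conc <- seg_conc[ok]

  ## --- cut segments at exposure changes ---------------------------------
  cat_c <- cat_c[in_window]
  cat_a <- cat_a[in_window]
  vtime <- vnum[in_window]
  ## exposure key per visit; boundary only where the key changes
  key <- paste(cat_c, cat_a, sep = "\r")
  starts <- ends <- concs <- numeric(0)
  pregs <- integer(0); cats_c <- cats_a <- character(0)
  for (s in seq_along(seg_start)) {
    a <- seg_start[s]; b <- seg_end[s]
    i0 <- findInterval(a, vtime)            # visit in effect at segment start
    inside <- which(vtime > a & vtime < b)
    cuts <- a
    cur <- key[i0]
    for (i in inside) {
      if (key[i] != cur) { cuts <- c(cuts, vtime[i]); cur <- key[i] }
    }
    cuts <- c(cuts, b)
    np <- length(cuts) - 1L
    idx <- findInterval(cuts[seq_len(np)], vtime)
    starts <- c(starts, cuts[seq_len(np)])
    ends <- c(ends, cuts[-1L])
    cats_c <- c(cats_c, cat_c[idx])
    cats_a <- c(cats_a, cat_a[idx])
    p <- integer(np); cc <- rep(NA_real_, np)
    if (seg_preg[s] == 1L) { p[np] <- 1L; cc[np] <- seg_conc[s] }
    pregs <- c(pregs, p); concs <- c(concs, cc)
  }

  list(
    woman_id = rep(wid, length(starts)),
    start = starts, end = ends,
    contraceptive = cats_c, art = cats_a,
    pregnancy = pregs, conception = concs
  )
}

## assemble column lists from .segment_one into a periods data frame
.periods_frame <- function(pieces, id_example) {
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  grab <- function(f) unlist(lapply(pieces, `[[`, f), use.names = FALSE)
  if (length(pieces) == 0L) {
    return(data.frame(
      woman_id = id_example[0], start_date = as.Date(character(0)),
      end_date = as.Date(character(0)), contraceptive = character(0),
      art = character(0), exposure_time = numeric(0), pregnancy = integer(0),
      conception_date = as.Date(character(0)), stringsAsFactors = FALSE
    ))
  }
  starts <- grab("start"); ends <- grab("end")
  data.frame(
    woman_id = grab("woman_id"),
    start_date = as.Date(starts, origin = "1970-01-01"),
    end_date = as.Date(ends, origin = "1970-01-01"),
    contraceptive = grab("contraceptive"),
    art = grab("art"),
    exposure_time = (ends - starts) / DAYS_PER_YEAR,
    pregnancy = grab("pregnancy"),
    conception_date = as.Date(grab("conception"), origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
}

## conception day per visit row (NA where no dateable report), vectorized
## over the whole table
.conception_column <- function(visits) {
  n <- nrow(visits)
  conc <- rep(NA_real_, n)
  rep_rows <- which(!is.na(visits$preg_reported) & visits$preg_reported)
  if (length(rep_rows)) {
    cd <- estimate_conception_date(
      lmp_date = if (is.null(visits$lmp_date)) NULL else visits$lmp_date[rep_rows],
      gest_age_weeks = if (is.null(visits$gest_age_weeks)) NULL else visits$gest_age_weeks[rep_rows],
      edd_date = if (is.null(visits$edd_date)) NULL else visits$edd_date[rep_rows],
      report_date = as.Date(visits$visit_date)[rep_rows],
      woman_id = visits$woman_id[rep_rows]
    )
    conc[rep_rows] <- as.numeric(cd)
  }
  conc
}

#' Segment one woman's visits into observation periods
#'
#' Partitions a woman's observation time (first to last visit on or before
#' `study_end`) into periods that break exactly where the contraceptive
#' category, the ART category, or pregnancy status changes. Upon an incident
#' pregnancy the woman is censored (not at risk) from the estimated
#' conception date either for 38 weeks (`FIXED_38_WEEKS`) or until the
#' recorded pregnancy-outcome date (`OUTCOME_RECORDS`, falling back to 38
#' weeks when no outcome is recorded); risk time resumes afterwards, so a
#' woman may contribute several pregnancies. Pregnancies conceived during
#' observation but reported at visits up to `lookahead_days` after
#' `study_end` are counted. Women with fewer than two visits contribute no
#' person-time and yield zero periods.
#'
#' @param visits Data frame of one woman's visits, sorted by `visit_date`,
#'   with columns `woman_id`, `visit_date`, and either precomputed
#'   `contraceptive_category`/`art_category` columns or raw
#'   `contraceptive_codes`/`art_drugs` label fields; pregnancy reports in
#'   `preg_reported` (logical) with optional `lmp_date`, `gest_age_weeks`,
#'   `edd_date`, `outcome_date`.
#' @param censor_rule `"FIXED_38_WEEKS"` or `"OUTCOME_RECORDS"`.
#' @param study_end Last calendar date of the study window.
#' @param lookahead_days Days past `study_end` during which pregnancy
#'   reports are still scanned (default 270, roughly nine months).
#' @return A data frame of observation periods with columns `woman_id`,
#'   `start_date`, `end_date`, `contraceptive`, `art`, `exposure_time`
#'   (years), `pregnancy` (0/1), `conception_date`.
#' @export
segment_periods <- function(visits, censor_rule = c("FIXED_38_WEEKS", "OUTCOME_RECORDS"),
                            study_end, lookahead_days = 270L) {
  censor_rule <- match.arg(censor_rule)
  vd <- as.Date(visits$visit_date)
  if (is.unsorted(as.numeric(vd))) stop("visits must be sorted by visit_date")
  if (is.null(visits$contraceptive_category)) {
    visits$contraceptive_category <- code_contraceptive_vec(visits$contraceptive_codes)
  }
  if (is.null(visits$art_category)) {
    visits$art_category <- code_art_vec(visits$art_drugs)
  }
  conc <- .conception_column(visits)
  outc <- if (is.null(visits$outcome_date)) rep(NA_real_, nrow(visits)) else as.numeric(as.Date(visits$outcome_date))
  piece <- .segment_one(
    wid = visits$woman_id[1L], vnum = as.numeric(vd),
    cat_c = visits$contraceptive_category, cat_a = visits$art_category,
    conception_num = conc, outcome_num = outc,
    censor_rule = censor_rule, end_num = as.numeric(as.Date(study_end)),
    lookahead_days = lookahead_days
  )
  .periods_frame(list(piece), visits$woman_id)
}

.covariate_cols <- c("age", "marital", "education", "n_children", "who_stage",
                     "cd4", "weight", "bmi", "anti_tb", "program")

#' Attach covariate snapshots to observation periods
#'
#' Each period receives the covariate values documented at the nearest visit
#' at or before its start date; values are held constant within the period
#' and missing values are propagated as missing (imputation is handled at
#' the estimation stage). Age is advanced to the period midpoint
#' (`avg_age`), and `calendar_year` is the decimal calendar year of the
#' midpoint.
#'
#' @param periods Periods from [segment_periods()] (any number of women).
#' @param visits The visit table the periods were derived from.
#' @return `periods` with covariate columns, `avg_age` and `calendar_year`
#'   appended.
#' @export
attach_covariates <- function(periods, visits) {
  if (nrow(periods) == 0L) {
    for (cl in c(.covariate_cols, "avg_age", "calendar_year")) periods[[cl]] <- numeric(0)
    return(periods)
  }
  vis <- visits[order(visits$woman_id, as.Date(visits$visit_date)), , drop = FALSE]
  vd <- as.numeric(as.Date(vis$visit_date))
  ## global lookup: for each period, last visit of the same woman at/before start
  ps <- as.numeric(periods$start_date)
  idx <- integer(nrow(periods))
  vsplit <- split(seq_len(nrow(vis)), vis$woman_id)
  psplit <- split(seq_len(nrow(periods)), periods$woman_id)
  for (w in names(psplit)) {
    vi <- vsplit[[w]]
    pi <- psplit[[w]]
    pos <- findInterval(ps[pi], vd[vi])
    pos[pos < 1L] <- 1L
    idx[pi] <- vi[pos]
  }
  for (cl in intersect(.covariate_cols, names(vis))) {
    periods[[cl]] <- vis[[cl]][idx]
  }
  mid <- (ps + as.numeric(periods$end_date)) / 2
  if (!is.null(periods$age)) {
    periods$avg_age <- periods$age + (mid - vd[idx]) / DAYS_PER_YEAR
  }
  periods$calendar_year <- 1970 + mid / DAYS_PER_YEAR
  periods
}

#' Code a visit-level cohort into observation periods
#'
#' Runs the full coding pipeline for a multi-woman visit table: exposure
#' category assignment, conception-date backdating, period segmentation
#' with pregnancy censoring, and covariate snapshotting.
#'
#' @inheritParams segment_periods
#' @param visits Visit table for the whole cohort (see [read_visits()] for
#'   the schema).
#' @param provenance Label recording which data source the visits came from
#'   (`"EMR"`, `"CHART"`, `"INTERVIEW"`, or `"RECONCILED"`).
#' @return An object of class `coded_cohort`: a list with `periods` (data
#'   frame), `provenance`, `women_count` (women contributing person-time)
#'   and `total_women_years`.
#' @export
code_cohort <- function(visits, censor_rule = "FIXED_38_WEEKS",
                        study_end = max(as.Date(visits$visit_date)),
                        lookahead_days = 270L, provenance = "EMR") {
  visits <- visits[order(visits$woman_id, as.Date(visits$visit_date)), , drop = FALSE]
  if (is.null(visits$contraceptive_category)) {
    visits$contraceptive_category <- code_contraceptive_vec(visits$contraceptive_codes)
  }
  if (is.null(visits$art_category)) {
    visits$art_category <- code_art_vec(visits$art_drugs)
  }
  censor_rule <- match.arg(censor_rule, c("FIXED_38_WEEKS", "OUTCOME_RECORDS"))
  vnum <- as.numeric(as.Date(visits$visit_date))
  conc <- .conception_column(visits)
  outc <- if (is.null(visits$outcome_date)) rep(NA_real_, nrow(visits)) else as.numeric(as.Date(visits$outcome_date))
  end_num <- as.numeric(as.Date(study_end))
  cat_c <- visits$contraceptive_category
  cat_a <- visits$art_category
  rows_by_woman <- split(seq_len(nrow(visits)),
                         factor(visits$woman_id, levels = unique(visits$woman_id)))
  plist <- lapply(rows_by_woman, function(ri) {
    .segment_one(
      wid = visits$woman_id[ri[1L]], vnum = vnum[ri],
      cat_c = cat_c[ri], cat_a = cat_a[ri],
      conception_num = conc[ri], outcome_num = outc[ri],
      censor_rule = censor_rule, end_num = end_num,
      lookahead_days = lookahead_days
    )
  })
  periods <- .periods_frame(plist, visits$woman_id)
  periods <- attach_covariates(periods, visits)
  structure(list(
    periods = periods,
    provenance = provenance,
    women_count = length(unique(periods$woman_id)),
    total_women_years = sum(periods$exposure_time)
  ), class = "coded_cohort")
}

#' @export
print.coded_cohort <- function(x, ...) {
  cat("Coded cohort (", x$provenance, "): ", x$women_count,
      " women contributing person-time, ", nrow(x$periods), " periods, ",
      format(round(x$total_women_years, 1), big.mark = ","), " women-years, ",
      sum(x$periods$pregnancy), " incident pregnancies\n", sep = "")
  invisible(x)
}

#' Read / write visit and period tables
#'
#' Visit tables are plain CSV, one row per clinic visit, with ISO-8601
#' dates and semicolon-delimited multi-valued label fields
#' (`contraceptive_codes`, `art_drugs`). Period tables mirror the
#' observation-period fields with uppercase category labels.
#'
#' @param path File path.
#' @param visits,periods Data frames to write.
#' @return `read_visits()` and `read_periods()` return data frames with
#'   date columns parsed as `Date`.
#' @name visits-io
#' @export
read_visits <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("visit_date", "lmp_date", "edd_date", "outcome_date"), names(v))) {
    v[[cl]] <- as.Date(v[[cl]])
  }
  v
}

#' @rdname visits-io
#' @export
write_visits <- function(visits, path) {
  utils::write.csv(visits, path, row.names = FALSE, na = "")
}

#' @rdname visits-io
#' @export
read_periods <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("start_date", "end_date", "conception_date"), names(p))) {
    p[[cl]] <- as.Date(p[[cl]])
  }
  p
}

#' @rdname visits-io
#' @export
write_periods <- function(periods, path) {
  utils::write.csv(periods, path, row.names = FALSE, na = "")
}
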