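# SDRE phenotyping: an insurant is a case when (a) at least one coded
# epilepsy diagnosis (ICD-10 G40*) appears anywhere in the observation
# window and (b) at least k distinct anticonvulsant substances (ATC class
# N03A at the 7-character level) each have a dispensation inside some
# rolling 18-month window whose end lies in the identification interval.
# The end of the earliest such window — the dispense date of the k-th
# substance — is the index date anchoring the 1-year baseline and three
# 365-day follow-up years.

#' Phenotyping configuration
#'
#' Parameters of the severe-drug-refractoriness case definition.
#'
#' @param epilepsy_icd_prefix ICD-10 prefix marking an epilepsy diagnosis
#'   (default `"G40"`).
#' @param aed_atc_prefix ATC prefix defining anticonvulsant substances
#'   (default `"N03A"`; N05-coded benzodiazepines never qualify).
#' @param k_distinct number of distinct substances required (default 4;
#'   must be >= 2).
#' @param window_days rolling window length in days; 18 months = 548 days.
#'   Window membership is half-open: a dispensation on day x counts for
#'   candidate index date d when `d - window_days < x <= d`.
#' @param identification_start,identification_end interval the index date
#'   must fall in (default calendar years 2009-2010). Earlier substances may
#'   precede it; only the k-th substance date is anchored.
#' @param baseline_days length of the pre-index baseline (default 365).
#' @param followup_years number of 365-day follow-up years (default 3).
#' @return object of class `phenotype_config`.
#' @export
phenotype_config <- function(epilepsy_icd_prefix = "G40",
                             aed_atc_prefix = "N03A",
                             k_distinct = 4L,
                             window_days = 548L,
                             identification_start = as.Date("2009-01-01"),
                             identification_end = as.Date("2010-12-31"),
                             baseline_days = 365L,
                             followup_years = 3L) {
  k_distinct <- as.integer(k_distinct)
  window_days <- as.integer(window_days)
  if (k_distinct < 2L) stopf("k_distinct must be >= 2")
  if (window_days <= 0L) stopf("window_days must be positive")
  identification_start <- as.Date(identification_start)
  identification_end <- as.Date(identification_end)
  if (identification_start > identification_end)
    stopf("identification interval is empty")
  structure(list(epilepsy_icd_prefix = epilepsy_icd_prefix,
                 aed_atc_prefix = aed_atc_prefix,
                 k_distinct = k_distinct,
                 window_days = window_days,
                 identification_start = identification_start,
                 identification_end = identification_end,
                 baseline_days = as.integer(baseline_days),
                 followup_years = as.integer(followup_years)),
            class = "phenotype_config")
}

#' Distinct-substance accrual order
#'
#' Reduces one insurant's dispensation history to the ordered first-dispense
#' dates of each distinct substance-level ATC code matching a prefix. Ties
#' on the date are broken by ATC code order.
#'
#' @param dispensations data frame of one insurant's dispensations
#'   (`dispense_date`, `atc_code`).
#' @param atc_prefix ATC prefix filter (default `"N03A"`).
#' @return data frame with columns `atc_code`, `first_dispense_date`, sorted
#'   by date then code.
#' @export
substance_accrual <- function(dispensations, atc_prefix = "N03A") {
  d <- dispensations[code_startswith(dispensations$atc_code, atc_prefix), ,
                     drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(atc_code = character(),
                      first_dispense_date = as.Date(character()),
                      stringsAsFactors = FALSE))
  d$atc_code <- toupper(d$atc_code)
  first <- tapply(as.numeric(d$dispense_date), d$atc_code, min)
  out <- data.frame(atc_code = names(first),
                    first_dispense_date = as.Date(as.numeric(first),
                                                  origin = "1970-01-01"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$first_dispense_date, out$atc_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find the rolling-window index date
#'
#' Scans one insurant's dispensation history for the earliest date `d` such
#' that `d` lies in the identification interval and at least `k_distinct`
#' distinct prefix-matching substances each have a dispensation in the
#' half-open window `(d - window_days, d]`. Candidate dates are the
#' dispense dates themselves (the distinct count can only rise at a
#' dispensation), so the returned date is the dispense date of the k-th
#' qualifying substance.
#'
#' @param dispensations data frame of one insurant's dispensations.
#' @param config a [phenotype_config()].
#' @return `NULL` when no window qualifies, otherwise a list with
#'   `index_date` and `qualifying_substances` (sorted ATC codes with a
#'   dispensation in the qualifying window).
#' @export
find_index_date <- function(dispensations, config = phenotype_config()) {
  d <- dispensations[code_startswith(dispensations$atc_code,
                                     config$aed_atc_prefix), , drop = FALSE]
  if (nrow(d) < config$k_distinct) return(NULL)
  dates <- as.Date(d$dispense_date)
  atc <- toupper(d$atc_code)
  cand <- sort(unique(dates[dates >= config$identification_start &
                              dates <= config$identification_end]))
  for (dd in cand) {
    dd <- as.Date(dd, origin = "1970-01-01")
    in_win <- dates > dd - config$window_days & dates <= dd
    subs <- unique(atc[in_win])
    if (length(subs) >= config$k_distinct)
      return(list(index_date = dd, qualifying_substances = sort(subs)))
  }
  NULL
}

#' Identify SDRE cases in a claims database
#'
#' Applies the full case definition: a coded epilepsy diagnosis (any
#' setting, any position, any time in the observation window), a qualifying
#' rolling-window index date from [find_index_date()], and enrollment
#' covering the index date.
#'
#' @param db a [claims_db()] object.
#' @param config a [phenotype_config()].
#' @return data frame of class `sdre_cases`, sorted by `insurant_id`, with
#'   columns `insurant_id`, `index_date`, `n_qualifying_substances`,
#'   `substances` (semicolon-joined ATC codes), `first_aed_date` (earliest
#'   prefix-matching dispensation ever) and `latency_days`
#'   (`index_date - first_aed_date`, the time from first to k-th substance).
#' @export
identify_sdre_cases <- function(db, config = phenotype_config()) {
  stopifnot(inherits(db, "claims_db"))
  epi_ids <- unique(db$diagnoses$insurant_id[
    code_startswith(db$diagnoses$icd_code, config$epilepsy_icd_prefix)])
  dp <- db$dispensations[db$dispensations$insurant_id %in% epi_ids &
                           code_startswith(db$dispensations$atc_code,
                                           config$aed_atc_prefix), ,
                         drop = FALSE]
  # cheap prefilter: k distinct substances overall are necessary
  n_distinct <- tapply(toupper(dp$atc_code), dp$insurant_id,
                       function(x) length(unique(x)))
  candidates <- names(n_distinct)[n_distinct >= config$k_distinct]
  rows <- list()
  for (id in sort(candidates)) {
    di <- dp[dp$insurant_id == id, , drop = FALSE]
    hit <- find_index_date(di, config)
    if (is.null(hit)) next
    ins <- db$insurants[db$insurants$insurant_id == id, , drop = FALSE]
    if (nrow(ins) == 0) next
    if (ins$enroll_start[1] > hit$index_date ||
        ins$enroll_end[1] < hit$index_date) next
    first_aed <- min(as.Date(di$dispense_date))
    rows[[length(rows) + 1]] <- data.frame(
      insurant_id = id,
      index_date = hit$index_date,
      n_qualifying_substances = length(hit$qualifying_substances),
      substances = paste(hit$qualifying_substances, collapse = ";"),
      first_aed_date = first_aed,
      latency_days = as.integer(hit$index_date - first_aed),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(insurant_id = character(), index_date = as.Date(character()),
               n_qualifying_substances = integer(), substances = character(),
               first_aed_date = as.Date(character()), latency_days = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sdre_cases", "data.frame")
  attr(out, "config") <- config
  out
}

#' Baseline and follow-up intervals for an index date
#'
#' Lays out the analysis periods anchored at a case's index date: baseline
#' `[index - baseline_days, index)`, follow-up year y
#' `[index + (y-1)*365, index + y*365)`, and `fu_total` spanning all
#' follow-up years. All intervals are half-open `[start, end)`.
#'
#' @param index_date Date vector of index (or pseudo-index) dates.
#' @param period one of `"baseline"`, `"fu1"`, `"fu2"`, `"fu3"`, ...,
#'   `"fu_total"`.
#' @param config a [phenotype_config()].
#' @return data frame with Date columns `start`, `end` aligned to
#'   `index_date`.
#' @export
case_intervals <- function(index_date, period, config = phenotype_config()) {
  index_date <- as.Date(index_date)
  if (period == "baseline") {
    data.frame(start = index_date - config$baseline_days, end = index_date)
  } else if (period == "fu_total") {
    data.frame(start = index_date,
               end = index_date + 365L * config$followup_years)
  } else if (grepl("^fu[0-9]+$", period)) {
    y <- as.integer(sub("^fu", "", period))
    if (y < 1 || y > config$followup_years)
      stopf("follow-up year %d outside configured range", y)
    data.frame(start = index_date + 365L * (y - 1L),
               end = index_date + 365L * y)
  } else {
    stopf("unknown period '%s'", period)
  }
}

all_periods <- function(config = phenotype_config()) {
  c("baseline", paste0("fu", seq_len(config$followup_years)), "fu_total")
}
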