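# Burden summaries: hospitalization, procedures, prescriptions, outpatient
# contacts, comorbidity prevalence and direct costs for a cohort over its
# index-anchored baseline and follow-up periods.
#
# Denominator policy: every proportion is denominated by the persons at risk
# (alive and enrolled) at the period start, and numerators are restricted to
# those persons, so numerator <= denominator always holds and deaths shrink
# later-year denominators monotonically. Day-level records (dispensations,
# admissions) enter a period by their date; quarter-level records
# (diagnoses, outpatient contacts) by the quarter midpoint. An admission
# belongs to the period containing its admit date even when the discharge
# crosses the boundary, and its stay counts both admission and discharge day
# (stay = discharge - admit + 1), matching DRG-style whole-case accounting.

# length of stay, counting both boundary days
los_days <- function(admit, discharge) {
  as.numeric(as.Date(discharge) - as.Date(admit)) + 1
}

#' At-risk status and exposure days within an interval
#'
#' A person is at risk in an interval when alive and enrolled at the
#' interval start; exposure days run from the interval start to the
#' earliest of interval end, death and disenrollment.
#'
#' @param insurant one or more rows of the insurant table (`enroll_start`,
#'   `enroll_end`, `death_date`).
#' @param start,end interval bounds, half-open `[start, end)`; recycled.
#' @return data frame with `at_risk` (logical) and `exposure_days`.
#' @export
person_period <- function(insurant, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  dd <- insurant$death_date
  at_risk <- insurant$enroll_start <= start & insurant$enroll_end >= start &
    (is.na(dd) | dd >= start)
  stop_day <- pmin(as.numeric(end) - 1,
                   ifelse(is.na(dd), Inf, as.numeric(dd)),
                   as.numeric(insurant$enroll_end))
  exposure <- pmax(stop_day - as.numeric(start) + 1, 0)
  exposure[!at_risk] <- 0
  data.frame(at_risk = at_risk, exposure_days = exposure)
}

# Cohort (insurant_id, index_date) -> per-person period bounds plus at-risk
# flags; shared entry point for every summary below.
cohort_at_risk <- function(db, cohort, period, config = phenotype_config()) {
  bounds <- case_intervals(cohort$index_date, period, config)
  ins <- db$insurants[match(cohort$insurant_id, db$insurants$insurant_id), ,
                      drop = FALSE]
  pp <- person_period(ins, bounds$start, bounds$end)
  data.frame(insurant_id = cohort$insurant_id, start = bounds$start,
             end = bounds$end, at_risk = pp$at_risk,
             exposure_days = pp$exposure_days, stringsAsFactors = FALSE)
}

burden_row <- function(cohort_label, period, metric, numerator, denominator,
                       value, dispersion = NA_real_) {
  data.frame(cohort = cohort_label, period = period, metric = metric,
             numerator = numerator, denominator = denominator, value = value,
             dispersion = dispersion, stringsAsFactors = FALSE)
}

# records of at-risk cohort members whose event date falls in their period
events_in_period <- function(events, date_col, ar) {
  m <- merge(events, ar[ar$at_risk, c("insurant_id", "start", "end")],
             by = "insurant_id")
  m[m[[date_col]] >= m$start & m[[date_col]] < m$end, , drop = FALSE]
}

#' Hospitalization summary over analysis periods
#'
#' For each period: proportion of at-risk persons with at least one
#' admission, total admissions, mean admissions per admitted person, total
#' hospital days and mean stay per admission. With `epilepsy_specific =
#' TRUE` only admissions whose primary diagnosis starts with one of
#' `epilepsy_icd_prefixes` (G40 epilepsy / G41 status epilepticus) count,
#' and metric names gain an `epilepsy_` prefix.
#'
#' @param db a [claims_db()].
#' @param cohort data frame with `insurant_id` and `index_date`.
#' @param periods which periods to summarise (see [case_intervals()]).
#' @param epilepsy_specific restrict to epilepsy-primary admissions.
#' @param cohort_label label written into the output rows.
#' @param epilepsy_icd_prefixes primary-ICD prefixes defining an
#'   epilepsy-specific admission.
#' @param config a [phenotype_config()].
#' @return burden table: data frame `cohort`, `period`, `metric`,
#'   `numerator`, `denominator`, `value`, `dispersion`. Undefined means
#'   (zero admissions) are reported as `NA`.
#' @export
hospitalization_summary <- function(db, cohort,
                                    periods = all_periods(config),
                                    epilepsy_specific = FALSE,
                                    cohort_label = "sdre",
                                    epilepsy_icd_prefixes = c("G40", "G41"),
                                    config = phenotype_config()) {
  adm <- db$admissions
  if (epilepsy_specific) {
    keep <- Reduce(`|`, lapply(epilepsy_icd_prefixes,
                               function(p) code_startswith(adm$primary_icd, p)))
    adm <- adm[keep, , drop = FALSE]
  }
  pre <- if (epilepsy_specific) "epilepsy_" else ""
  out <- list()
  for (period in periods) {
    ar <- cohort_at_risk(db, cohort, period, config)
    n_risk <- sum(ar$at_risk)
    a <- events_in_period(adm, "admit_date", ar)
    n_admitted <- length(unique(a$insurant_id))
    n_adm <- nrow(a)
    days <- sum(los_days(a$admit_date, a$discharge_date))
    out[[length(out) + 1]] <- rbind(
      burden_row(cohort_label, period, paste0(pre, "hospitalized_prop"),
                 n_admitted, n_risk,
                 if (n_risk > 0) n_admitted / n_risk else NA_real_),
      burden_row(cohort_label, period, paste0(pre, "admissions_total"),
                 n_adm, NA_real_, n_adm),
      burden_row(cohort_label, period,
                 paste0(pre, "admissions_per_admitted_mean"), n_adm,
                 n_admitted,
                 if (n_admitted > 0) n_adm / n_admitted else NA_real_),
      burden_row(cohort_label, period, paste0(pre, "hospital_days_total"),
                 days, NA_real_, days),
      burden_row(cohort_label, period,
                 paste0(pre, "stay_per_admission_mean_days"), days, n_adm,
                 if (n_adm > 0) days / n_adm else NA_real_))
  }
  do.call(rbind, out)
}

#' Procedure uptake by OPS prefix
#'
#' Proportion of at-risk cohort members with at least one admission in the
#' period carrying an OPS procedure code matching each prefix (e.g.
#' `"8-972"` complex epilepsy treatment, `"1-210"` non-invasive video-EEG
#' monitoring, `"5-010"` brain surgery).
#'
#' @inheritParams hospitalization_summary
#' @param ops_prefixes character vector of OPS prefixes; a malformed prefix
#'   (not digit-dash-digits) is fatal.
#' @return burden table rows with metric `ops_<prefix>_prop`.
#' @export
procedure_uptake <- function(db, cohort,
                             ops_prefixes = c("8-972", "1-210", "5-010"),
                             periods = c("fu1", "fu2", "fu3", "fu_total"),
                             cohort_label = "sdre",
                             config = phenotype_config()) {
  bad <- !grepl("^[0-9]-[0-9]{2,3}(\\.[0-9a-z]+)?$", ops_prefixes)
  if (any(bad)) stopf("malformed OPS prefix '%s'", ops_prefixes[bad][1])
  adm <- db$admissions
  code_list <- split_codes(adm$ops_codes)
  out <- list()
  for (period in periods) {
    ar <- cohort_at_risk(db, cohort, period, config)
    n_risk <- sum(ar$at_risk)
    idx <- which(adm$insurant_id %in% ar$insurant_id[ar$at_risk])
    for (p in ops_prefixes) {
      has <- idx[vapply(code_list[idx],
                        function(v) any(code_startswith(v, p)), logical(1))]
      a <- events_in_period(adm[has, , drop = FALSE], "admit_date", ar)
      n_with <- length(unique(a$insurant_id))
      out[[length(out) + 1]] <- burden_row(
        cohort_label, period, paste0("ops_", p, "_prop"), n_with, n_risk,
        if (n_risk > 0) n_with / n_risk else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Proportion hospitalized for status epilepticus during follow-up
#'
#' Patient-level proportion of the cohort with at least one admission whose
#' primary diagnosis starts with G41 within the follow-up years; repeat
#' admissions count once.
#'
#' @inheritParams hospitalization_summary
#' @param icd_prefix primary-ICD prefix (default `"G41"`).
#' @return list with `n` (patients), `denominator` (at risk at follow-up
#'   start) and `proportion`.
#' @export
status_epilepticus_hospitalized <- function(db, cohort, icd_prefix = "G41",
                                            config = phenotype_config()) {
  ar <- cohort_at_risk(db, cohort, "fu_total", config)
  adm <- db$admissions[code_startswith(db$admissions$primary_icd, icd_prefix), ,
                       drop = FALSE]
  a <- events_in_period(adm, "admit_date", ar)
  n <- length(unique(a$insurant_id))
  denom <- sum(ar$at_risk)
  list(n = n, denominator = denom,
       proportion = if (denom > 0) n / denom else NA_real_)
}

#' Prescription patterns by substance and period
#'
#' Per substance-level ATC code and period, the share of at-risk cohort
#' members with at least one dispensation (a patient counts once per period
#' per substance regardless of pack count), plus patient-level statistics of
#' the number of distinct substances dispensed over the whole follow-up
#' (mean and SD, zero-substance patients included).
#'
#' @inheritParams hospitalization_summary
#' @param atc_prefix substance filter (default `"N03A"`).
#' @return list with `shares` (data frame `atc_code`, `substance_name`,
#'   `period`, `n`, `denominator`, `share`) and `distinct` (list `mean`,
#'   `sd`, `n`, counts over `fu_total`).
#' @export
prescription_pattern <- function(db, cohort, periods = all_periods(config),
                                 atc_prefix = "N03A",
                                 config = phenotype_config()) {
  dp <- db$dispensations[code_startswith(db$dispensations$atc_code,
                                         atc_prefix), , drop = FALSE]
  dp$atc_code <- toupper(dp$atc_code)
  shares <- list()
  for (period in periods) {
    ar <- cohort_at_risk(db, cohort, period, config)
    n_risk <- sum(ar$at_risk)
    d <- events_in_period(dp, "dispense_date", ar)
    if (nrow(d)) {
      tab <- unique(d[, c("insurant_id", "atc_code", "substance_name")])
      cnt <- stats::aggregate(insurant_id ~ atc_code + substance_name,
                              data = tab, FUN = length)
      names(cnt)[3] <- "n"
    } else {
      cnt <- data.frame(atc_code = character(), substance_name = character(),
                        n = integer(), stringsAsFactors = FALSE)
    }
    if (nrow(cnt)) {
      cnt$period <- period
      cnt$denominator <- n_risk
      cnt$share <- if (n_risk > 0) cnt$n / n_risk else NA_real_
      shares[[length(shares) + 1]] <-
        cnt[, c("atc_code", "substance_name", "period", "n", "denominator",
                "share")]
    }
  }
  shares <- if (length(shares)) do.call(rbind, shares) else
    data.frame(atc_code = character(), substance_name = character(),
               period = character(), n = integer(), denominator = integer(),
               share = numeric(), stringsAsFactors = FALSE)
  ar <- cohort_at_risk(db, cohort, "fu_total", config)
  d <- events_in_period(dp, "dispense_date", ar)
  per_patient <- tapply(d$atc_code, d$insurant_id,
                        function(x) length(unique(x)))
  counts <- rep(0L, sum(ar$at_risk))
  names(counts) <- ar$insurant_id[ar$at_risk]
  counts[names(per_patient)] <- as.integer(per_patient)
  list(shares = shares,
       distinct = list(mean = if (length(counts)) mean(counts) else NA_real_,
                       sd = if (length(counts) > 1) stats::sd(counts) else
                         NA_real_,
                       n = length(counts), counts = counts))
}

#' Two-proportion test for a substance's share change between periods
#'
#' Chi-square comparison of the share of patients with at least one
#' dispensation of a substance in two periods, the hook used to flag
#' significant prescription shifts between baseline and follow-up.
#'
#' @param pattern result of [prescription_pattern()].
#' @param atc_code substance to compare.
#' @param period_a,period_b periods to compare.
#' @return [chi_square_2x2()] result plus the two shares.
#' @export
share_change_test <- function(pattern, atc_code, period_a, period_b) {
  sh <- pattern$shares
  pick <- function(period) {
    r <- sh[sh$atc_code == toupper(atc_code) & sh$period == period, ,
            drop = FALSE]
    if (nrow(r) == 0) {
      denom <- sh$denominator[sh$period == period][1]
      list(n = 0L, denom = if (is.na(denom)) 0L else denom)
    } else list(n = r$n[1], denom = r$denominator[1])
  }
  a <- pick(period_a); b <- pick(period_b)
  res <- chi_square_2x2(a$n, a$denom - a$n, b$n, b$denom - b$n)
  res$share_a <- a$n / a$denom
  res$share_b <- b$n / b$denom
  res
}

#' Outpatient contact summary by specialty and period
#'
#' Per specialty and period: share of at-risk persons with at least one
#' contact, mean contacts among those with any, and the share whose
#' anticonvulsant prescriber is that specialty; plus an `any` row with the
#' overall mean contacts per at-risk person.
#'
#' @inheritParams hospitalization_summary
#' @return data frame `cohort`, `period`, `specialty`, `n_any`,
#'   `denominator`, `share_any`, `mean_contacts_among_any`,
#'   `prescriber_share`, `mean_contacts_per_person`.
#' @export
contact_summary <- function(db, cohort, periods = all_periods(config),
                            cohort_label = "sdre",
                            config = phenotype_config()) {
  op <- db$outpatient
  op$mid <- quarter_midpoint(op$quarter)
  out <- list()
  for (period in periods) {
    ar <- cohort_at_risk(db, cohort, period, config)
    n_risk <- sum(ar$at_risk)
    o <- events_in_period(op, "mid", ar)
    total_contacts <- sum(o$n_contacts)
    specs <- sort(unique(o$specialty))
    for (s in specs) {
      os_ <- o[o$specialty == s, , drop = FALSE]
      per <- tapply(os_$n_contacts, os_$insurant_id, sum)
      presc <- unique(os_$insurant_id[os_$prescriber_of_aed])
      out[[length(out) + 1]] <- data.frame(
        cohort = cohort_label, period = period, specialty = s,
        n_any = length(per), denominator = n_risk,
        share_any = if (n_risk > 0) length(per) / n_risk else NA_real_,
        mean_contacts_among_any = if (length(per)) mean(per) else NA_real_,
        prescriber_share = if (n_risk > 0) length(presc) / n_risk else
          NA_real_,
        mean_contacts_per_person = NA_real_, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- data.frame(
      cohort = cohort_label, period = period, specialty = "any",
      n_any = length(unique(o$insurant_id)), denominator = n_risk,
      share_any = if (n_risk > 0) length(unique(o$insurant_id)) / n_risk else
        NA_real_,
      mean_contacts_among_any = NA_real_,
      prescriber_share = NA_real_,
      mean_contacts_per_person = if (n_risk > 0) total_contacts / n_risk else
        NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare diagnosis prevalence between cases and controls
#'
#' Proportion of each cohort with at least one diagnosis in the ICD code
#' set during the period (quarter midpoints locate quarter-level records),
#' with a Pearson chi-square test of the difference.
#'
#' @param db a [claims_db()].
#' @param cases,controls cohort data frames (`insurant_id`, `index_date`;
#'   controls use their pseudo-index).
#' @param set a [code_set()].
#' @param period analysis period (default `"fu1"`, the first follow-up
#'   year).
#' @param config a [phenotype_config()].
#' @return list: `p_case`, `p_control`, `n_case`, `n_control`,
#'   `denom_case`, `denom_control`, `statistic`, `p_value`.
#' @export
prevalence_compare <- function(db, cases, controls, set, period = "fu1",
                               config = phenotype_config()) {
  stopifnot(inherits(set, "code_set"))
  dg <- db$diagnoses
  if (set$settings == "inpatient_primary")
    dg <- dg[dg$setting == "inpatient" & dg$position == "primary", ,
             drop = FALSE]
  dg <- dg[icd_in_set(dg$icd_code, set), , drop = FALSE]
  dg$mid <- quarter_midpoint(dg$quarter)
  count <- function(cohort) {
    ar <- cohort_at_risk(db, cohort, period, config)
    d <- events_in_period(dg, "mid", ar)
    list(n = length(unique(d$insurant_id)), denom = sum(ar$at_risk))
  }
  a <- count(cases); b <- count(controls)
  ts <- chi_square_2x2(a$n, a$denom - a$n, b$n, b$denom - b$n)
  list(p_case = a$n / a$denom, p_control = b$n / b$denom,
       n_case = a$n, n_control = b$n,
       denom_case = a$denom, denom_control = b$denom,
       statistic = ts$statistic, p_value = ts$p_value)
}

#' Direct cost summary by period
#'
#' Component sums over the cohort per period: inpatient (G-DRG admission
#' cost), medication (dispensation cost), outpatient visit fees, ancillary
#' treatment, special equipment and dialysis, with the total equal to the
#' component sum to the cent, an epilepsy-specific inpatient subtotal
#' (primary ICD G40/G41), and per-person-year means.
#'
#' In `"index_anchored"` mode periods are the case-anchored intervals of
#' [case_intervals()]; in `"calendar"` mode they are calendar years
#' (baseline 2010, follow-up years 2011-2013), mirroring billing-year
#' accounting.
#'
#' @inheritParams hospitalization_summary
#' @param mode `"index_anchored"` or `"calendar"`.
#' @param calendar_baseline_year first calendar year when `mode =
#'   "calendar"`.
#' @return data frame, one row per period: the six components, `total`,
#'   `epilepsy_inpatient`, `n_at_risk`, `person_years`,
#'   `total_per_person_year`.
#' @export
cost_summary <- function(db, cohort, periods = all_periods(config),
                         mode = c("index_anchored", "calendar"),
                         cohort_label = "sdre",
                         calendar_baseline_year = 2010L,
                         epilepsy_icd_prefixes = c("G40", "G41"),
                         config = phenotype_config()) {
  mode <- match.arg(mode)
  if (any(db$admissions$drg_cost < 0, na.rm = TRUE) ||
      any(db$dispensations$cost < 0, na.rm = TRUE))
    stopf("negative cost in data; run validate_claims()")
  op <- db$outpatient
  op$mid <- quarter_midpoint(op$quarter)
  dp <- db$dispensations
  adm <- db$admissions
  epi <- Reduce(`|`, lapply(epilepsy_icd_prefixes,
                            function(p) code_startswith(adm$primary_icd, p)))
  out <- list()
  for (period in periods) {
    if (mode == "index_anchored") {
      ar <- cohort_at_risk(db, cohort, period, config)
    } else {
      yrs <- calendar_period_years(period, calendar_baseline_year, config)
      start <- as.Date(sprintf("%d-01-01", yrs[1]))
      end <- as.Date(sprintf("%d-01-01", yrs[length(yrs)] + 1L))
      ins <- db$insurants[match(cohort$insurant_id,
                                db$insurants$insurant_id), , drop = FALSE]
      pp <- person_period(ins, start, end)
      ar <- data.frame(insurant_id = cohort$insurant_id, start = start,
                       end = end, at_risk = pp$at_risk,
                       exposure_days = pp$exposure_days,
                       stringsAsFactors = FALSE)
    }
    a <- events_in_period(adm, "admit_date", ar)
    a_epi <- events_in_period(adm[epi, , drop = FALSE], "admit_date", ar)
    d <- events_in_period(dp, "dispense_date", ar)
    o <- events_in_period(op, "mid", ar)
    comp <- c(inpatient = round(sum(a$drg_cost), 2),
              medication = round(sum(d$cost), 2),
              outpatient = round(sum(o$cost), 2),
              ancillary = round(sum(o$ancillary_cost), 2),
              equipment = round(sum(o$equipment_cost), 2),
              dialysis = round(sum(o$dialysis_cost), 2))
    py <- sum(ar$exposure_days) / 365
    out[[length(out) + 1]] <- data.frame(
      cohort = cohort_label, period = period, t(comp),
      total = round(sum(comp), 2),
      epilepsy_inpatient = round(sum(a_epi$drg_cost), 2),
      n_at_risk = sum(ar$at_risk), person_years = py,
      total_per_person_year = if (py > 0) sum(comp) / py else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

calendar_period_years <- function(period, baseline_year, config) {
  fu <- baseline_year + seq_len(config$followup_years)
  if (period == "baseline") return(baseline_year)
  if (period == "fu_total") return(fu)
  if (grepl("^fu[0-9]+$", period)) {
    y <- as.integer(sub("^fu", "", period))
    if (y >= 1 && y <= config$followup_years) return(fu[y])
  }
  stopf("unknown period '%s'", period)
}
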