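# Fixture builders, all generated in code at test time.

# Hand-written miniature database: 3 insurants, 5 dispensations, a little of
# everything else.
tiny_db <- function() {
  claims_db(
    insurants = data.frame(
      insurant_id = c("A01", "A02", "A03"),
      birth_year = c(1970L, 1985L, 2001L),
      sex = c("female", "male", "male"),
      enroll_start = as.Date(c("2008-01-01", "2008-01-01", "2009-06-01")),
      enroll_end = as.Date(c("2013-12-31", "2012-06-30", "2013-12-31")),
      death_date = as.Date(c(NA, "2012-06-30", NA))),
    diagnoses = data.frame(
      insurant_id = c("A01", "A01", "A02"),
      quarter = c("2009Q1", "2010Q3", "2009Q2"),
      icd_code = c("G40.2", "G40.2", "I10"),
      setting = c("outpatient", "outpatient", "outpatient"),
      position = c("primary", "primary", "secondary")),
    dispensations = data.frame(
      insurant_id = c("A01", "A01", "A01", "A02", "A03"),
      dispense_date = as.Date(c("2009-01-15", "2009-05-02", "2009-11-20",
                                "2010-02-01", "2011-07-07")),
      atc_code = c("N03AX14", "N03AX09", "N03AX14", "C07AB02", "N03AG01"),
      substance_name = c("levetiracetam", "lamotrigine", "levetiracetam",
                         "metoprolol", "valproate"),
      cost = c(120.5, 80.25, 120.5, 15.1, 60)),
    admissions = data.frame(
      insurant_id = c("A01", "A02"),
      admit_date = as.Date(c("2009-03-10", "2011-11-01")),
      discharge_date = as.Date(c("2009-03-15", "2011-11-01")),
      primary_icd = c("G40.2", "I21.0"),
      secondary_icds = c("F32.1;I10", ""),
      ops_codes = c("8-972.2", ""),
      drg_cost = c(3500.75, 4200)),
    outpatient = data.frame(
      insurant_id = c("A01", "A02"),
      quarter = c("2009Q1", "2010Q2"),
      specialty = c("neurologist", "general_practitioner"),
      n_contacts = c(2L, 1L),
      prescriber_of_aed = c(TRUE, FALSE),
      cost = c(80.4, 35),
      ancillary_cost = c(0, 12.5),
      equipment_cost = c(0, 0),
      dialysis_cost = c(0, 0)))
}

# Cohort database encoding aggregate admission counts exactly: `n_cohort`
# patients share one index date; `n_admitted` of them hold `n_admissions`
# admissions totalling `total_days` hospital days (admissions spread
# round-robin, days split as evenly as integers allow).
aggregate_admissions_db <- function(n_cohort, n_admitted, n_admissions,
                                    total_days, primary_icd = "G40.9",
                                    index_date = as.Date("2009-07-01"),
                                    ids = sprintf("C%04d", seq_len(n_cohort))) {
  stopifnot(n_admitted <= n_cohort, n_admissions >= n_admitted,
            total_days >= n_admissions)
  ins <- data.frame(
    insurant_id = ids, birth_year = 1970L, sex = "male",
    enroll_start = as.Date("2008-01-01"), enroll_end = as.Date("2013-12-31"),
    death_date = as.Date(NA), stringsAsFactors = FALSE)
  who <- rep(ids[seq_len(n_admitted)], length.out = n_admissions)
  base_len <- total_days %/% n_admissions
  extra <- total_days %% n_admissions
  los <- rep(base_len, n_admissions) + c(rep(1, extra),
                                         rep(0, n_admissions - extra))
  # admissions packed into follow-up year 1, capped so discharges stay inside
  admit <- index_date + (seq_len(n_admissions) %% 300)
  adm <- data.frame(insurant_id = who, admit_date = admit,
                    discharge_date = admit + los - 1,
                    primary_icd = primary_icd, secondary_icds = "",
                    ops_codes = "", drg_cost = 1000,
                    stringsAsFactors = FALSE)
  list(db = claims_db(insurants = ins, admissions = adm),
       cohort = data.frame(insurant_id = ids, index_date = index_date,
                           stringsAsFactors = FALSE))
}

# Naive per-patient loop recomputation of the hospitalization summary, used
# as the burden-module oracle on small databases.
naive_hospitalization <- function(db, cohort, period,
                                  config = phenotype_config()) {
  n_risk <- 0; admitted <- 0; n_adm <- 0; days <- 0
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$insurant_id[i]
    iv <- case_intervals(cohort$index_date[i], period, config)
    ins <- db$insurants[db$insurants$insurant_id == id, ]
    alive <- is.na(ins$death_date) || ins$death_date >= iv$start
    enrolled <- ins$enroll_start <= iv$start && ins$enroll_end >= iv$start
    if (!(alive && enrolled)) next
    n_risk <- n_risk + 1
    a <- db$admissions[db$admissions$insurant_id == id, ]
    a <- a[a$admit_date >= iv$start & a$admit_date < iv$end, ]
    if (nrow(a) > 0) {
      admitted <- admitted + 1
      n_adm <- n_adm + nrow(a)
      days <- days + sum(as.numeric(a$discharge_date - a$admit_date) + 1)
    }
  }
  list(n_risk = n_risk, admitted = admitted, n_adm = n_adm, days = days)
}

# Memoised default small simulation shared across test files.
cached_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_claims(default_params("small", seed = 7L))
    cache
  }
})

# Small matching playground: `n_per_stratum` epilepsy-free insurants in each
# of a few birth-year/sex strata, plus case insurants with G40 diagnoses.
matching_db <- function(case_birth_years, case_sexes, n_per_stratum = 30) {
  strata <- unique(data.frame(birth_year = case_birth_years,
                              sex = case_sexes, stringsAsFactors = FALSE))
  pool <- do.call(rbind, lapply(seq_len(nrow(strata)), function(s)
    data.frame(insurant_id = sprintf("K%02d%03d", s, seq_len(n_per_stratum)),
               birth_year = strata$birth_year[s], sex = strata$sex[s],
               stringsAsFactors = FALSE)))
  n_cases <- length(case_birth_years)
  cases_ins <- data.frame(insurant_id = sprintf("CASE%02d", seq_len(n_cases)),
                          birth_year = case_birth_years, sex = case_sexes,
                          stringsAsFactors = FALSE)
  ins <- rbind(pool, cases_ins)
  ins$enroll_start <- as.Date("2008-01-01")
  ins$enroll_end <- as.Date("2013-12-31")
  ins$death_date <- as.Date(NA)
  diag <- data.frame(insurant_id = cases_ins$insurant_id, quarter = "2009Q1",
                     icd_code = "G40.9", setting = "outpatient",
                     position = "primary", stringsAsFactors = FALSE)
  list(db = claims_db(insurants = ins, diagnoses = diag),
       cases = data.frame(insurant_id = cases_ins$insurant_id,
                          index_date = as.Date("2009-07-01"),
                          stringsAsFactors = FALSE))
}
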