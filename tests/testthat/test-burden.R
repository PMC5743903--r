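test_that("at-risk and exposure follow death and enrollment", {
  ins <- data.frame(
    insurant_id = c("a", "b", "c"), birth_year = 1970L, sex = "male",
    enroll_start = as.Date("2008-01-01"), enroll_end = as.Date("2013-12-31"),
    death_date = as.Date(c(NA, "2010-03-01", "2009-09-15")))
  idx <- as.Date("2009-07-01")
  fu1 <- case_intervals(idx, "fu1")
  fu2 <- case_intervals(idx, "fu2")
  pp1 <- person_period(ins, fu1$start, fu1$end)
  pp2 <- person_period(ins, fu2$start, fu2$end)
  # survivor: fully exposed each year
  expect_true(pp1$at_risk[1]); expect_equal(pp1$exposure_days[1], 365)
  # death in fu1: at risk in fu1 with partial exposure, gone by fu2
  expect_true(pp1$at_risk[3])
  expect_equal(pp1$exposure_days[3], as.numeric(ins$death_date[3] - idx) + 1)
  expect_lt(pp1$exposure_days[3], 365)
  expect_false(pp2$at_risk[3])
  expect_equal(pp2$exposure_days[3], 0)
  # death before fu2 start (but after fu1): at risk only in fu1
  expect_true(pp1$at_risk[2]); expect_false(pp2$at_risk[2])
})

test_that("hospitalization summary reproduces encoded aggregate arithmetic", {
  # all-cause totals: 568 admitted of 769, 2403 admissions, 23346 days
  fx <- aggregate_admissions_db(769, 568, 2403, 23346)
  b <- hospitalization_summary(fx$db, fx$cohort, periods = "fu_total")
  val <- function(m) b$value[b$metric == m]
  expect_equal(val("hospitalized_prop"), 568 / 769)
  expect_equal(val("admissions_total"), 2403)
  expect_equal(val("admissions_per_admitted_mean"), 2403 / 568)  # ~4.2
  expect_equal(val("hospital_days_total"), 23346)
  expect_equal(val("stay_per_admission_mean_days"), 23346 / 2403)  # ~9.7

  # epilepsy-specific totals: 353 patients, 1002 admissions, 10474 days
  fe <- aggregate_admissions_db(769, 353, 1002, 10474, primary_icd = "G40.1")
  be <- hospitalization_summary(fe$db, fe$cohort, periods = "fu_total",
                                epilepsy_specific = TRUE)
  vale <- function(m) be$value[be$metric == m]
  expect_equal(vale("epilepsy_admissions_per_admitted_mean"), 1002 / 353)
  expect_equal(vale("epilepsy_stay_per_admission_mean_days"), 10474 / 1002)

  # a non-epilepsy primary is excluded by the epilepsy-specific filter
  fo <- aggregate_admissions_db(10, 5, 8, 40, primary_icd = "I21.0")
  bo <- hospitalization_summary(fo$db, fo$cohort, periods = "fu_total",
                                epilepsy_specific = TRUE)
  expect_equal(bo$value[bo$metric == "epilepsy_admissions_total"], 0)
  expect_true(is.na(bo$value[bo$metric ==
                               "epilepsy_admissions_per_admitted_mean"]))
})

test_that("procedure uptake counts patients once per prefix and validates prefixes", {
  fx <- aggregate_admissions_db(769, 105, 140, 300)
  fx$db$admissions$ops_codes <- "8-972.0"
  b <- procedure_uptake(fx$db, fx$cohort, ops_prefixes = "8-972",
                        periods = "fu_total")
  expect_equal(b$value, 105 / 769)  # 13.6%
  b2 <- procedure_uptake(fx$db, fx$cohort, ops_prefixes = "1-210",
                         periods = "fu_total")
  expect_equal(b2$value, 0)
  expect_error(procedure_uptake(fx$db, fx$cohort, ops_prefixes = "972"),
               "malformed")
})

test_that("status epilepticus admissions are a patient-level follow-up proportion", {
  fx <- aggregate_admissions_db(769, 94, 188, 400, primary_icd = "G41.0")
  se <- status_epilepticus_hospitalized(fx$db, fx$cohort)
  expect_equal(se$n, 94)
  expect_equal(se$proportion, 94 / 769)  # 12.2%, repeats counted once
  fx2 <- aggregate_admissions_db(100, 10, 15, 40, primary_icd = "G40.9")
  expect_equal(status_epilepticus_hospitalized(fx2$db, fx2$cohort)$proportion,
               0)
})

test_that("prescription shares count a patient once per period per substance", {
  ids <- sprintf("C%04d", 1:769)
  idx <- as.Date("2009-07-01")
  ins <- data.frame(insurant_id = ids, birth_year = 1970L, sex = "male",
                    enroll_start = as.Date("2008-01-01"),
                    enroll_end = as.Date("2013-12-31"),
                    death_date = as.Date(NA))
  # 435 patients on levetiracetam in fu1 (two packs each: still one patient),
  # nobody in fu2
  disp <- data.frame(insurant_id = rep(ids[1:435], 2),
                     dispense_date = rep(idx + c(10, 40), each = 435),
                     atc_code = "N03AX14", substance_name = "levetiracetam",
                     cost = 100)
  db <- claims_db(insurants = ins, dispensations = disp)
  cohort <- data.frame(insurant_id = ids, index_date = idx)
  pat <- prescription_pattern(db, cohort, periods = c("fu1", "fu2",
                                                      "fu_total"))
  sh <- pat$shares
  expect_equal(sh$share[sh$period == "fu_total"], 435 / 769)  # 56.6%
  expect_equal(sh$n[sh$period == "fu1"], 435L)
  expect_false("fu2" %in% sh$period)  # no one counted outside their period
  # distinct-substance statistics over follow-up include the zeros
  expect_equal(pat$distinct$mean, 435 / 769)
  one_each <- prescription_pattern(db, cohort[1:435, ],
                                   periods = "fu_total")$distinct
  expect_equal(one_each$mean, 1)
  expect_equal(one_each$sd, 0)
})

test_that("contact summary reports share, mean among attenders and prescriber share", {
  ins <- data.frame(insurant_id = c("u", "v"), birth_year = 1970L,
                    sex = "male", enroll_start = as.Date("2008-01-01"),
                    enroll_end = as.Date("2013-12-31"),
                    death_date = as.Date(NA))
  op <- data.frame(insurant_id = "u",
                   quarter = c("2009Q3", "2009Q4"),
                   specialty = "general_practitioner",
                   n_contacts = c(3L, 2L), prescriber_of_aed = c(TRUE, FALSE),
                   cost = 50, ancillary_cost = 0, equipment_cost = 0,
                   dialysis_cost = 0)
  db <- claims_db(insurants = ins, outpatient = op)
  cohort <- data.frame(insurant_id = c("u", "v"),
                       index_date = as.Date("2009-07-01"))
  cs <- contact_summary(db, cohort, periods = "fu1")
  gp <- cs[cs$specialty == "general_practitioner", ]
  expect_equal(gp$share_any, 1 / 2)
  expect_equal(gp$mean_contacts_among_any, 5)
  expect_equal(gp$prescriber_share, 1 / 2)
  any_row <- cs[cs$specialty == "any", ]
  expect_equal(any_row$mean_contacts_per_person, 5 / 2)
  # the single-attender view: share 100%, mean 5 contacts
  cs1 <- contact_summary(db, cohort[1, ], periods = "fu1")
  expect_equal(cs1$share_any[cs1$specialty == "general_practitioner"], 1)
})

test_that("prevalence comparison applies range semantics and the closed-form chi-square", {
  ids_case <- sprintf("A%04d", 1:769)
  ids_ctrl <- sprintf("B%05d", 1:15380)
  idx <- as.Date("2009-07-01")
  ins <- data.frame(insurant_id = c(ids_case, ids_ctrl), birth_year = 1970L,
                    sex = "male", enroll_start = as.Date("2008-01-01"),
                    enroll_end = as.Date("2013-12-31"),
                    death_date = as.Date(NA))
  # 215/769 cases and 1538/15380 controls diagnosed in follow-up year 1
  diag <- data.frame(insurant_id = c(ids_case[1:215], ids_ctrl[1:1538]),
                     quarter = "2009Q4", icd_code = "F32.9",
                     setting = "outpatient", position = "secondary")
  db <- claims_db(insurants = ins, diagnoses = diag)
  cases <- data.frame(insurant_id = ids_case, index_date = idx)
  ctrls <- data.frame(insurant_id = ids_ctrl, index_date = idx)
  res <- prevalence_compare(db, cases, ctrls, code_set("depression",
                                                       "F32-F33"))
  expect_equal(res$p_case, 215 / 769)      # 28.0%
  expect_equal(res$p_control, 1538 / 15380)  # 10.0%
  e <- outer(c(769, 15380), c(215 + 1538, 769 + 15380 - 215 - 1538)) / 16149
  o <- matrix(c(215, 1538, 769 - 215, 15380 - 1538), 2)
  expect_equal(res$statistic, sum((o - e)^2 / e), tolerance = 1e-9)
  expect_lt(res$p_value, 0.001)

  # identical cohorts give equal proportions and a null statistic
  same <- prevalence_compare(db, cases, cases, code_set("depression",
                                                        "F32-F33"))
  expect_equal(same$p_case, same$p_control)
  expect_equal(same$statistic, 0)

  # range matching is on the first three characters
  expect_true(icd_in_set("S06.1", code_set("head", "S00-S09")))
  expect_false(icd_in_set("S10.0", code_set("head", "S00-S09")))
})

test_that("cost summary conserves totals and applies the epilepsy primary-ICD rule", {
  ins <- data.frame(insurant_id = "w", birth_year = 1970L, sex = "male",
                    enroll_start = as.Date("2008-01-01"),
                    enroll_end = as.Date("2013-12-31"),
                    death_date = as.Date(NA))
  adm <- data.frame(insurant_id = "w", admit_date = as.Date("2009-08-01"),
                    discharge_date = as.Date("2009-08-05"),
                    primary_icd = "G40.2", secondary_icds = "",
                    ops_codes = "", drg_cost = 3000)
  db <- claims_db(insurants = ins, admissions = adm)
  cohort <- data.frame(insurant_id = "w", index_date = as.Date("2009-07-01"))
  cs <- cost_summary(db, cohort, periods = "fu1")
  expect_equal(cs$inpatient, 3000)
  expect_equal(cs$epilepsy_inpatient, 3000)
  expect_equal(cs$total, 3000)

  # empty cohort: all zeros
  cs0 <- cost_summary(db, cohort[0, ], periods = "fu1")
  expect_equal(cs0$total, 0)

  # simulated database: the total equals the component sum to the cent in
  # every period, in both accounting modes
  sim <- cached_small_sim()
  cases <- identify_sdre_cases(sim$db)
  for (mode in c("index_anchored", "calendar")) {
    cc <- cost_summary(sim$db, cases[, c("insurant_id", "index_date")],
                       mode = mode)
    comp_sum <- rowSums(cc[, c("inpatient", "medication", "outpatient",
                               "ancillary", "equipment", "dialysis")])
    expect_equal(cc$total, round(comp_sum, 2), tolerance = 1e-9)
    expect_true(all(cc$epilepsy_inpatient <= cc$inpatient + 1e-9))
  }
})

test_that("summaries equal a naive per-patient loop on a small database", {
  p <- sim_params(n_insurants = 150L, epilepsy_prevalence = 0.3,
                  refractory_fraction = 0.5, seed = 21L)
  sim <- simulate_claims(p)
  cases <- identify_sdre_cases(sim$db)
  expect_gt(nrow(cases), 3)
  cohort <- cases[, c("insurant_id", "index_date")]
  for (period in c("baseline", "fu1", "fu2", "fu3", "fu_total")) {
    want <- naive_hospitalization(sim$db, cohort, period)
    b <- hospitalization_summary(sim$db, cohort, periods = period)
    expect_equal(b$numerator[b$metric == "hospitalized_prop"], want$admitted)
    expect_equal(b$denominator[b$metric == "hospitalized_prop"], want$n_risk)
    expect_equal(b$value[b$metric == "admissions_total"], want$n_adm)
    expect_equal(b$value[b$metric == "hospital_days_total"], want$days)
  }
})

test_that("follow-up totals add up across the annual periods", {
  sim <- cached_small_sim()
  cases <- identify_sdre_cases(sim$db)
  cohort <- cases[, c("insurant_id", "index_date")]
  b <- hospitalization_summary(sim$db, cohort)
  tot <- function(metric, period) b$value[b$metric == metric &
                                            b$period == period]
  expect_equal(tot("admissions_total", "fu_total"),
               sum(sapply(c("fu1", "fu2", "fu3"),
                          function(p) tot("admissions_total", p))))
  expect_equal(tot("hospital_days_total", "fu_total"),
               sum(sapply(c("fu1", "fu2", "fu3"),
                          function(p) tot("hospital_days_total", p))))
  # ">=1 ever" dominates each annual proportion
  for (p in c("fu1", "fu2", "fu3"))
    expect_gte(tot("hospitalized_prop", "fu_total"),
               tot("hospitalized_prop", p))
  # deaths shrink later-year at-risk denominators monotonically
  den <- sapply(c("fu1", "fu2", "fu3"),
                function(p) b$denominator[b$metric == "hospitalized_prop" &
                                            b$period == p])
  expect_true(all(diff(den) <= 0))
})
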