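one_disp <- function(dates, atcs) {
  data.frame(insurant_id = "X", dispense_date = as.Date(dates),
             atc_code = atcs, substance_name = "s", cost = 0,
             stringsAsFactors = FALSE)
}

test_that("substance accrual keeps first dates per distinct substance, in order", {
  d <- one_disp(rep("2009-03-01", 5), rep("N03AX14", 5))
  expect_identical(nrow(substance_accrual(d)), 1L)

  d <- one_disp(c("2009-01-01", "2009-02-01", "2009-03-01", "2009-04-01"),
                c("N03AX14", "N03AX09", "N03AX14", "N03AG01"))
  acc <- substance_accrual(d)
  expect_equal(acc$atc_code, c("N03AX14", "N03AX09", "N03AG01"))
  expect_equal(acc$first_dispense_date,
               as.Date(c("2009-01-01", "2009-02-01", "2009-04-01")))

  # non-N03A benzodiazepines (lorazepam N05BA06) never count
  d <- one_disp(c("2009-01-01", "2009-02-01"), c("N05BA06", "N05BA06"))
  expect_identical(nrow(substance_accrual(d, "N03A")), 0L)

  # date ties break by ATC code order
  d <- one_disp(rep("2009-01-01", 2), c("N03AX14", "N03AG01"))
  expect_equal(substance_accrual(d)$atc_code, c("N03AG01", "N03AX14"))
})

test_that("index date is the fourth-substance date when the span fits the window", {
  base <- as.Date("2009-01-10")
  d <- one_disp(base + c(0, 100, 200, 300),
                c("N03AX14", "N03AX09", "N03AG01", "N03AX18"))
  hit <- find_index_date(d)
  expect_equal(hit$index_date, base + 300)
  expect_setequal(hit$qualifying_substances,
                  c("N03AX14", "N03AX09", "N03AG01", "N03AX18"))

  # three lifetime substances can never qualify
  d <- one_disp(base + c(0, 10, 20), c("N03AX14", "N03AX09", "N03AG01"))
  expect_null(find_index_date(d))

  # firsts spread over > 548 days: only a re-dispensation inside the window
  # can rescue the oldest substance
  d0 <- one_disp(base + c(0, 200, 400, 600),
                 c("N03AX14", "N03AX09", "N03AG01", "N03AX18"))
  expect_null(find_index_date(d0))
  d1 <- rbind(d0, one_disp(base + 580, "N03AX14"))
  hit <- find_index_date(d1)
  # the window ending at the fourth substance (day 600) now holds all four,
  # because the day-580 re-dispensation keeps the first substance inside
  expect_equal(hit$index_date, base + 600)
  expect_equal(find_index_date(d1)$index_date,
               brute_force_index(d1)$index_date)
})

test_that("window scan agrees with brute-force enumeration on fuzzed histories", {
  withr::local_seed(101)
  cfg <- phenotype_config()
  for (i in 1:200) {
    h <- random_history()
    got <- find_index_date(h, cfg)
    want <- brute_force_index(h, cfg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$index_date, want$index_date)
      expect_equal(got$qualifying_substances, want$qualifying_substances)
    }
  }
})

test_that("adding a dispensation never moves the index date later", {
  withr::local_seed(55)
  for (i in 1:100) {
    h <- random_history(30)
    before <- find_index_date(h)
    extra <- random_history(1)
    after <- find_index_date(rbind(h, extra))
    if (!is.null(before)) {
      expect_false(is.null(after))
      expect_lte(as.numeric(after$index_date), as.numeric(before$index_date))
    }
  }
})

test_that("shifting a history by +30 days shifts the index date by +30 days", {
  base <- as.Date("2009-03-01")
  h <- one_disp(base + c(0, 60, 120, 200, 250),
                c("N03AX14", "N03AX09", "N03AG01", "N03AX18", "N03AX14"))
  before <- find_index_date(h)
  h30 <- h
  h30$dispense_date <- h30$dispense_date + 30
  after <- find_index_date(h30)
  expect_equal(after$index_date, before$index_date + 30)
})

test_that("case identification requires diagnosis, window and enrollment together", {
  ins <- data.frame(
    insurant_id = c("P1", "P2", "P3"), birth_year = 1980L, sex = "female",
    enroll_start = as.Date(c("2008-01-01", "2008-01-01", "2010-06-01")),
    enroll_end = as.Date("2013-12-31"), death_date = as.Date(NA))
  subs <- c("N03AX14", "N03AX09", "N03AG01", "N03AX18", "N03AX11")
  disp <- do.call(rbind, lapply(c("P1", "P2", "P3"), function(id) {
    d <- one_disp(as.Date("2009-02-01") + c(0, 50, 100, 150, 200), subs)
    d$insurant_id <- id
    d
  }))
  diag <- data.frame(insurant_id = c("P1", "P3"), quarter = "2009Q2",
                     icd_code = "G40.1", setting = "outpatient",
                     position = "primary")
  db <- claims_db(insurants = ins, diagnoses = diag, dispensations = disp)
  cases <- identify_sdre_cases(db)
  # P2 lacks the diagnosis; P3 is not enrolled at the index date
  expect_identical(cases$insurant_id, "P1")
  expect_equal(cases$index_date, as.Date("2009-02-01") + 150)
  expect_equal(cases$n_qualifying_substances, 4L)
  expect_equal(cases$latency_days, 150L)
})

test_that("phenotyping recovers the generator's refractory set exactly at default caps", {
  sim <- cached_small_sim()
  cases <- identify_sdre_cases(sim$db)
  truth_ids <- sim$truth$insurant_id[sim$truth$is_refractory]
  expect_setequal(cases$insurant_id, truth_ids)
  m <- merge(cases, sim$truth, by = "insurant_id")
  expect_true(all(m$index_date == m$true_index_date))
})
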