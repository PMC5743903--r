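test_that("controls match case strata exactly and inherit the pseudo-index", {
  fx <- matching_db(case_birth_years = c(1970L, 1970L, 1985L),
                    case_sexes = c("male", "male", "female"),
                    n_per_stratum = 60)
  m <- match_controls(fx$db, fx$cases, ratio = 20, seed = 3)
  expect_identical(nrow(m$pairs), 60L)
  expect_identical(nrow(m$shortfalls), 0L)
  ins <- fx$db$insurants
  joined <- merge(merge(m$pairs, ins, by.x = "control_id",
                        by.y = "insurant_id"),
                  ins, by.x = "case_id", by.y = "insurant_id",
                  suffixes = c("_control", "_case"))
  expect_true(all(joined$birth_year_control == joined$birth_year_case))
  expect_true(all(joined$sex_control == joined$sex_case))
  expect_true(all(m$pseudo_index$pseudo_index == fx$cases$index_date[1]))
  # sampling without replacement: no control serves two cases
  expect_false(any(duplicated(m$pairs$control_id)))
  # post-match marginal age/sex distribution is the case distribution x ratio
  ctrl_strata <- table(paste(joined$birth_year_control, joined$sex_control))
  mi <- match(fx$cases$insurant_id, ins$insurant_id)
  case_strata <- table(paste(ins$birth_year[mi], ins$sex[mi]))
  expect_equal(as.vector(ctrl_strata[names(case_strata)]),
               20 * as.vector(case_strata))
})

test_that("no matched control carries an epilepsy code; pool exhaustion is a shortfall", {
  fx <- matching_db(case_birth_years = 1970L, case_sexes = "male",
                    n_per_stratum = 5)
  # give one pool member a G40 diagnosis: it must never be sampled
  db <- fx$db
  extra <- data.frame(insurant_id = db$insurants$insurant_id[1],
                      quarter = "2012Q4", icd_code = "G40.8",
                      setting = "outpatient", position = "secondary")
  db <- claims_db(insurants = db$insurants,
                  diagnoses = rbind(db$diagnoses, extra),
                  observation_start = db$observation_start,
                  observation_end = db$observation_end)
  m <- match_controls(db, fx$cases, ratio = 20, seed = 3)
  expect_identical(nrow(m$pairs), 4L)
  expect_false(db$insurants$insurant_id[1] %in% m$pairs$control_id)
  expect_identical(m$shortfalls$matched, 4L)
  expect_identical(m$shortfalls$requested, 20L)
})

test_that("matching is deterministic and stable per case under case removal", {
  fx <- matching_db(case_birth_years = c(1960L, 1972L, 1984L),
                    case_sexes = c("female", "male", "female"),
                    n_per_stratum = 50)
  m1 <- match_controls(fx$db, fx$cases, ratio = 10, seed = 9)
  m2 <- match_controls(fx$db, fx$cases, ratio = 10, seed = 9)
  expect_identical(m1$pairs, m2$pairs)
  # distinct strata: dropping one case leaves the others' control sets alone
  m3 <- match_controls(fx$db, fx$cases[-2, ], ratio = 10, seed = 9)
  for (cid in fx$cases$insurant_id[-2])
    expect_identical(m3$pairs$control_id[m3$pairs$case_id == cid],
                     m1$pairs$control_id[m1$pairs$case_id == cid])
  # a different seed reshuffles
  m4 <- match_controls(fx$db, fx$cases, ratio = 10, seed = 10)
  expect_false(identical(m1$pairs$control_id, m4$pairs$control_id))
})

test_that("controls must be enrolled at the case's index date", {
  fx <- matching_db(case_birth_years = 1970L, case_sexes = "male",
                    n_per_stratum = 10)
  db <- fx$db
  db$insurants$enroll_start[1:5] <- as.Date("2011-01-01")  # after index
  m <- match_controls(db, fx$cases, ratio = 20, seed = 1)
  expect_identical(sort(m$pairs$control_id),
                   sort(db$insurants$insurant_id[6:10]))
})

test_that("matched control demographics track the generator's case mix", {
  sim <- cached_small_sim()
  cases <- identify_sdre_cases(sim$db)
  m <- match_controls(sim$db, cases, ratio = 20, seed = 2)
  ins <- sim$db$insurants
  j <- merge(merge(m$pairs, ins, by.x = "control_id", by.y = "insurant_id"),
             ins, by.x = "case_id", by.y = "insurant_id",
             suffixes = c("_control", "_case"))
  expect_true(all(j$birth_year_control == j$birth_year_case))
  expect_true(all(j$sex_control == j$sex_case))
  epi_ids <- unique(sim$db$diagnoses$insurant_id[
    startsWith(sim$db$diagnoses$icd_code, "G40")])
  expect_length(intersect(m$pairs$control_id, epi_ids), 0)
})
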