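# Synthetic statutory-claims generator with known ground truth. Emulates the
# structure of a 5% population-representative German insurance research
# database over 2008-2013 (quarterly outpatient billing, day-level
# dispensations and admissions) at reduced scale, so every downstream stage
# is testable without access to real sickness-fund data.
#
# Default rates are anchored to the published SDRE aggregates: case admission
# rate 2403/769/3 per person-year with epilepsy fraction 1002/2403, control
# rate 8461/15380/3; piecewise mortality hazards reproducing 7.8% first-year
# and 14% three-year case risk against 2.1% in three years for the
# background; drug-accrual pacing aimed at the ~212-day first-to-fourth
# substance latency and ~5.3 distinct substances over follow-up.

default_aed_pool <- function() {
  data.frame(
    atc_code = c("N03AX14", "N03AX09", "N03AG01", "N03AX18", "N03AX11",
                 "N03AF01", "N03AF02", "N03AX16", "N03AX12", "N03AB02",
                 "N03AE01", "N03AX15", "N03AX22", "N03AA02"),
    substance_name = c("levetiracetam", "lamotrigine", "valproate",
                       "lacosamide", "topiramate", "carbamazepine",
                       "oxcarbazepine", "pregabalin", "gabapentin",
                       "phenytoin", "clonazepam", "zonisamide", "perampanel",
                       "phenobarbital"),
    weight = c(0.16, 0.13, 0.13, 0.09, 0.08, 0.08, 0.06, 0.06, 0.05, 0.04,
               0.04, 0.04, 0.02, 0.02),
    stringsAsFactors = FALSE)
}

# Coarse German-like age/sex pyramid (reference year 2010).
default_pyramid <- function() {
  bands <- data.frame(
    age_low = c(0, 18, 40, 65, 80),
    age_high = c(17, 39, 64, 79, 89),
    share = c(0.165, 0.265, 0.365, 0.155, 0.05),
    male = c(0.51, 0.505, 0.50, 0.47, 0.35))
  out <- rbind(
    data.frame(age_low = bands$age_low, age_high = bands$age_high,
               sex = "male", weight = bands$share * bands$male),
    data.frame(age_low = bands$age_low, age_high = bands$age_high,
               sex = "female", weight = bands$share * (1 - bands$male)))
  out[order(out$age_low, out$sex), ]
}

# Per-follow-up-year diagnosis probabilities by ICD block, cases vs controls.
default_comorbidities <- function() {
  data.frame(
    name = c("depression", "organic_mental", "somatoform", "personality",
             "gastrointestinal", "vascular", "hypertension", "head_injury",
             "trunk_limb_injury", "knee_lower_leg_injury",
             "ankle_foot_injury"),
    icd_code = c("F32.1", "F06.8", "F45.0", "F07.0", "K21.0", "I63.9",
                 "I10", "S06.0", "T14.0", "S82.0", "S92.0"),
    p_case = c(0.28, 0.248, 0.208, 0.196, 0.26, 0.22, 0.30, 0.16, 0.16,
               0.06, 0.05),
    p_control = c(0.10, 0.05, 0.08, 0.02, 0.13, 0.05, 0.30, 0.03, 0.08,
                  0.03, 0.03),
    stringsAsFactors = FALSE)
}

#' Simulation parameters for the synthetic claims generator
#'
#' All rates are the study conditions the generator emulates; they are
#' checked for coherence (probabilities in \[0,1\], non-negative hazards,
#' refractory substance-switch probability strictly above the
#' non-refractory one so the phenotype is learnable, a substance pool large
#' enough to accrue four distinct drugs).
#'
#' @param n_insurants cohort size.
#' @param observation_start,observation_end observation window.
#' @param age_sex_pyramid data frame `age_low`, `age_high`, `sex`, `weight`.
#' @param epilepsy_prevalence probability of carrying epilepsy.
#' @param refractory_fraction probability of severe refractoriness among
#'   epileptics.
#' @param aed_pool data frame `atc_code` (7-character N03A codes),
#'   `substance_name`, `weight`.
#' @param accrual_gap_mean_days,accrual_gap_max_days exponential mean and
#'   cap (days) of the gaps between successive new substances during the
#'   forced four-substance accrual of refractory insurants. The cap keeps
#'   the first-to-fourth span under the 548-day window, so every refractory
#'   insurant is recoverable by the rolling-window scan.
#' @param index_window_start,index_window_end interval the generated
#'   fourth-substance date falls in (defaults match the phenotyping
#'   identification interval, calendar 2009-2010).
#' @param switch_prob_refractory,switch_prob_nonrefractory per-quarter
#'   probability of adding a previously unused substance after therapy
#'   start; must satisfy refractory > non-refractory.
#' @param max_nonrefractory_substances lifetime substance cap for
#'   non-refractory epileptics (default 3: below the phenotype threshold, so
#'   case identification is exact; raise it to study overlapping regimes).
#' @param admission_rate_case,admission_rate_control all-cause admissions
#'   per person-year.
#' @param admission_dispersion_case,admission_dispersion_control gamma
#'   frailty shape per cohort: each person's admission rate is the cohort
#'   rate times a Gamma(shape, shape) multiplier, giving
#'   negative-binomial admission counts. Smaller values concentrate
#'   admissions in fewer people (set `Inf` for plain Poisson). The defaults
#'   make the share with any admission per year and over three years agree
#'   with the published proportions at the published mean rates.
#' @param epilepsy_admission_fraction fraction of case admissions with an
#'   epilepsy primary diagnosis; of those, `status_epilepticus_fraction`
#'   carry G41 rather than G40.
#' @param ops_complex_prob,ops_video_eeg_prob,ops_surgery_prob per
#'   epilepsy-admission probabilities of OPS 8-972.x complex treatment,
#'   1-210 video-EEG monitoring, 5-010 brain surgery.
#' @param los_meanlog,los_sdlog lognormal length-of-stay parameters (days).
#' @param case_hazard_year1,case_hazard_later piecewise-constant annual
#'   mortality hazards of cases from their index date.
#' @param background_hazard annual mortality hazard of everyone else, from
#'   observation start.
#' @param comorbidity_profile data frame `name`, `icd_code`, `p_case`,
#'   `p_control`: per-year Bernoulli diagnosis probabilities by ICD block.
#' @param drg_cost_meanlog,drg_cost_sdlog lognormal per-admission G-DRG
#'   cost (EUR).
#' @param dispensation_cost_meanlog,dispensation_cost_sdlog lognormal
#'   per-dispensation cost (EUR).
#' @param contact_cost_meanlog,contact_cost_sdlog lognormal per-contact
#'   outpatient fee (EUR).
#' @param enrollment_gap_prob probability an insurant enrolls late or
#'   disenrolls early (uniform truncation); insurance churn is otherwise
#'   absent.
#' @param seed master seed; per-table sub-streams are derived from it.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_insurants = 20000L,
                       observation_start = as.Date("2008-01-01"),
                       observation_end = as.Date("2013-12-31"),
                       age_sex_pyramid = default_pyramid(),
                       epilepsy_prevalence = 0.008,
                       refractory_fraction = 0.10,
                       aed_pool = default_aed_pool(),
                       accrual_gap_mean_days = 80,
                       accrual_gap_max_days = 175,
                       index_window_start = as.Date("2009-01-01"),
                       index_window_end = as.Date("2010-12-31"),
                       switch_prob_refractory = 0.11,
                       switch_prob_nonrefractory = 0.02,
                       max_nonrefractory_substances = 3L,
                       admission_rate_case = 2403 / 769 / 3,
                       admission_rate_control = 8461 / 15380 / 3,
                       admission_dispersion_case = 0.8,
                       admission_dispersion_control = 0.25,
                       epilepsy_admission_fraction = 1002 / 2403,
                       status_epilepticus_fraction = 0.12,
                       ops_complex_prob = 0.20,
                       ops_video_eeg_prob = 0.06,
                       ops_surgery_prob = 0.04,
                       los_meanlog = log(7), los_sdlog = 0.8,
                       case_hazard_year1 = -log(1 - 0.078),
                       case_hazard_later = log((1 - 0.078) / (1 - 0.14)) / 2,
                       background_hazard = -log(1 - 0.021) / 3,
                       comorbidity_profile = default_comorbidities(),
                       drg_cost_meanlog = log(4000), drg_cost_sdlog = 0.6,
                       dispensation_cost_meanlog = log(250),
                       dispensation_cost_sdlog = 0.5,
                       contact_cost_meanlog = log(35),
                       contact_cost_sdlog = 0.3,
                       enrollment_gap_prob = 0,
                       seed = 1L) {
  p <- structure(as.list(environment()), class = "sim_params")
  probs <- c(epilepsy_prevalence, refractory_fraction,
             switch_prob_refractory, switch_prob_nonrefractory,
             epilepsy_admission_fraction, status_epilepticus_fraction,
             ops_complex_prob, ops_video_eeg_prob, ops_surgery_prob,
             enrollment_gap_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  if (refractory_fraction > 0 && switch_prob_refractory <= switch_prob_nonrefractory)
    stopf("refractory switch probability must exceed the non-refractory one")
  if (any(c(case_hazard_year1, case_hazard_later, background_hazard,
            admission_rate_case, admission_rate_control) < 0))
    stopf("hazards and rates must be non-negative")
  if (any(c(admission_dispersion_case, admission_dispersion_control) <= 0))
    stopf("admission dispersion (gamma shape) must be positive")
  if (refractory_fraction > 0 && nrow(aed_pool) < 4)
    stopf("substance pool too small to accrue four distinct drugs")
  if (accrual_gap_max_days * 3 >= 548)
    stopf("accrual gap cap must keep the four-substance span inside 548 days")
  if (observation_start >= observation_end) stopf("empty observation window")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$n_insurants, "insurants,",
      format(x$observation_start), "to", format(x$observation_end), "\n")
  cat(sprintf("  epilepsy prevalence %.4f, refractory fraction %.4f, seed %d\n",
              x$epilepsy_prevalence, x$refractory_fraction, x$seed))
  invisible(x)
}

#' Default simulation parameter sets
#'
#' `"small"` is sized for interactive use and testing (20,000 insurants,
#' elevated refractory fraction so a workable number of cases appears).
#' `"paper_like"` scales the published setting down to 200,000 insurants and
#' sets the refractory fraction so the expected case count matches the
#' published yield of 769 cases among four million insured
#' (769/4,000,000 of the population).
#'
#' @param scale `"small"` or `"paper_like"`.
#' @param seed master seed.
#' @return a [sim_params()] object.
#' @export
default_params <- function(scale = c("small", "paper_like"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "small") {
    sim_params(n_insurants = 20000L, epilepsy_prevalence = 0.008,
               refractory_fraction = 0.10, seed = seed)
  } else {
    sim_params(n_insurants = 200000L, epilepsy_prevalence = 0.008,
               refractory_fraction = (769 / 4e6) / 0.008, seed = seed)
  }
}

## ---- generator -------------------------------------------------------------

#' Simulate a synthetic claims database with ground truth
#'
#' Generates insurants from the age/sex pyramid, assigns epilepsy and
#' severe-refractoriness flags, builds drug histories as per-insurant
#' quarterly stay/add processes over the N03A substance pool (refractory
#' insurants accrue four distinct substances within a guaranteed
#' sub-548-day span ending in the index window), draws deaths from
#' piecewise-constant hazards (cases from index, background from
#' observation start), and sprinkles admissions, comorbidity diagnoses,
#' outpatient contacts and costs at the configured rates. All records are
#' truncated at death and at disenrollment. The same parameters and seed
#' reproduce the output exactly.
#'
#' @param params a [sim_params()] object.
#' @return list with `db` (a [claims_db()] passing [validate_claims()]) and
#'   `truth` (data frame: `insurant_id`, `has_epilepsy`, `is_refractory`,
#'   `true_index_date`, `death_date`, `n_admissions`).
#' @export
simulate_claims <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  os <- params$observation_start; oe <- params$observation_end
  n <- params$n_insurants

  ins <- with_seed(substream_seed(params$seed, "insurants"),
                   sim_insurants(params))
  flags <- with_seed(substream_seed(params$seed, "flags"), {
    has_ep <- stats::runif(n) < params$epilepsy_prevalence
    is_refr <- has_ep & (stats::runif(n) < params$refractory_fraction)
    list(has_ep = has_ep, is_refr = is_refr)
  })

  drugs <- with_seed(substream_seed(params$seed, "drugs"),
                     sim_drug_histories(params, ins, flags))

  death <- with_seed(substream_seed(params$seed, "deaths"),
                     sim_deaths(params, ins, flags, drugs$true_index))
  ins$death_date <- death
  ins$death_date[!is.na(death) & death > ins$enroll_end] <-
    NA  # death after disenrollment is unobserved
  # insurance coverage terminates at death
  dd <- !is.na(ins$death_date)
  ins$enroll_end[dd] <- ins$death_date[dd]
  end_of_follow <- pmin(ifelse(is.na(ins$death_date), as.numeric(oe),
                               as.numeric(ins$death_date)),
                        as.numeric(ins$enroll_end))
  end_of_follow <- as.Date(end_of_follow, origin = "1970-01-01")

  disp <- drugs$dispensations
  if (nrow(disp)) {
    keep <- disp$dispense_date <= end_of_follow[match(disp$insurant_id,
                                                      ins$insurant_id)] &
      disp$dispense_date >= ins$enroll_start[match(disp$insurant_id,
                                                   ins$insurant_id)]
    disp <- disp[keep, , drop = FALSE]
  }

  diag_epi <- with_seed(substream_seed(params$seed, "diagnoses"),
                        sim_epilepsy_diagnoses(params, ins, flags,
                                               drugs$first_aed,
                                               end_of_follow))
  diag_com <- with_seed(substream_seed(params$seed, "comorbidities"),
                        sim_comorbidities(params, ins, flags, end_of_follow))

  adm <- with_seed(substream_seed(params$seed, "admissions"),
                   sim_admissions(params, ins, flags, end_of_follow))
  diag_inpat <- if (nrow(adm$admissions)) {
    data.frame(insurant_id = adm$admissions$insurant_id,
               quarter = quarter_of(adm$admissions$admit_date),
               icd_code = adm$admissions$primary_icd,
               setting = "inpatient", position = "primary",
               stringsAsFactors = FALSE)
  } else NULL

  outp <- with_seed(substream_seed(params$seed, "outpatient"),
                    sim_outpatient(params, ins, flags, end_of_follow))

  db <- claims_db(insurants = ins,
                  diagnoses = rbind(diag_epi, diag_com, diag_inpat),
                  dispensations = disp,
                  admissions = adm$admissions,
                  outpatient = outp,
                  observation_start = os, observation_end = oe)
  n_adm <- tabulate(match(adm$admissions$insurant_id, ins$insurant_id), n)
  truth <- data.frame(insurant_id = ins$insurant_id,
                      has_epilepsy = flags$has_ep,
                      is_refractory = flags$is_refr,
                      true_index_date = drugs$true_index,
                      death_date = ins$death_date,
                      n_admissions = n_adm,
                      stringsAsFactors = FALSE)
  list(db = db, truth = truth)
}

sim_insurants <- function(params) {
  n <- params$n_insurants
  pyr <- params$age_sex_pyramid
  band <- sample.int(nrow(pyr), n, replace = TRUE, prob = pyr$weight)
  age <- pyr$age_low[band] +
    floor(stats::runif(n) * (pyr$age_high[band] - pyr$age_low[band] + 1))
  ref_year <- as.integer(format(params$observation_start, "%Y")) + 2L
  os <- params$observation_start; oe <- params$observation_end
  start <- rep(os, n); end <- rep(oe, n)
  if (params$enrollment_gap_prob > 0) {
    span <- as.numeric(oe - os)
    gap <- stats::runif(n) < params$enrollment_gap_prob
    late <- gap & stats::runif(n) < 0.5
    cut <- round(stats::runif(n, 0.05, 0.45) * span)
    start[late] <- os + cut[late]
    end[gap & !late] <- oe - cut[gap & !late]
  }
  birth_year <- ref_year - age
  # children born inside the window enroll at birth, not before
  start <- pmax(start, as.Date(sprintf("%d-01-01", birth_year)))
  data.frame(insurant_id = sprintf("P%07d", seq_len(n)),
             birth_year = birth_year,
             sex = pyr$sex[band],
             enroll_start = start, enroll_end = end,
             death_date = as.Date(NA),
             stringsAsFactors = FALSE)
}

# Quarterly refill dates for one substance from its first dispense date.
refill_dates <- function(first, until) {
  if (until < first) return(as.Date(character()))
  n_q <- as.integer(as.numeric(until - first) %/% 91)
  if (n_q < 1) return(first)
  offs <- 91 * seq_len(n_q) + sample(-14:14, n_q, replace = TRUE)
  d <- first + offs[offs > 0]
  c(first, d[d <= until])
}

sim_drug_histories <- function(params, ins, flags) {
  n <- params$n_insurants
  pool <- params$aed_pool
  true_index <- rep(as.Date(NA), n)
  first_aed <- rep(as.Date(NA), n)
  os <- params$observation_start; oe <- params$observation_end
  rows <- list()
  for (i in which(flags$has_ep)) {
    id <- ins$insurant_id[i]
    if (flags$is_refr[i]) {
      gaps <- pmin(stats::rexp(3, 1 / params$accrual_gap_mean_days),
                   params$accrual_gap_max_days) + 1
      span <- round(sum(gaps))
      lo <- max(params$index_window_start, os + span)
      t4 <- lo + floor(stats::runif(1) *
                         (as.numeric(params$index_window_end - lo) + 1))
      firsts <- t4 - rev(round(cumsum(rev(gaps))))
      firsts <- c(firsts, t4)  # first-dispense dates of substances 1..4
      subs <- sample(pool$atc_code, 4, prob = pool$weight)
      true_index[i] <- t4
      # post-index additions: per-quarter chance of a previously unused drug
      q_starts <- if (t4 + 91 <= oe) seq(t4 + 91, oe, by = 91) else
        as.Date(character())
      remaining <- setdiff(pool$atc_code, subs)
      for (qs in q_starts) {
        if (!length(remaining)) break
        if (stats::runif(1) < params$switch_prob_refractory) {
          new <- sample(remaining, 1)
          remaining <- setdiff(remaining, new)
          subs <- c(subs, new)
          firsts <- c(firsts, as.Date(qs, origin = "1970-01-01") +
                        sample(0:89, 1))
        }
      }
    } else {
      first <- os + floor(stats::runif(1) * (as.numeric(oe - os) - 90))
      subs <- sample(pool$atc_code, 1, prob = pool$weight)
      firsts <- first
      cap <- params$max_nonrefractory_substances
      q_starts <- if (first + 91 <= oe) seq(first + 91, oe, by = 91) else
        as.Date(character())
      remaining <- setdiff(pool$atc_code, subs)
      for (qs in q_starts) {
        if (length(subs) >= cap || !length(remaining)) break
        if (stats::runif(1) < params$switch_prob_nonrefractory) {
          new <- sample(remaining, 1)
          remaining <- setdiff(remaining, new)
          subs <- c(subs, new)
          firsts <- c(firsts, as.Date(qs, origin = "1970-01-01") +
                        sample(0:89, 1))
        }
      }
    }
    firsts <- as.Date(pmin(pmax(as.numeric(firsts), as.numeric(os)),
                           as.numeric(oe)), origin = "1970-01-01")
    first_aed[i] <- min(firsts)
    dates <- lapply(seq_along(subs),
                    function(k) refill_dates(firsts[k], oe))
    lens <- lengths(dates)
    rows[[length(rows) + 1]] <- data.frame(
      insurant_id = id,
      dispense_date = as.Date(unlist(dates), origin = "1970-01-01"),
      atc_code = rep(subs, lens),
      stringsAsFactors = FALSE)
  }
  disp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(insurant_id = character(),
               dispense_date = as.Date(character()),
               atc_code = character(), stringsAsFactors = FALSE)
  if (nrow(disp)) {
    disp$substance_name <- params$aed_pool$substance_name[
      match(disp$atc_code, params$aed_pool$atc_code)]
    disp$cost <- round(stats::rlnorm(nrow(disp),
                                     params$dispensation_cost_meanlog,
                                     params$dispensation_cost_sdlog), 2)
  } else {
    disp$substance_name <- character(0)
    disp$cost <- numeric(0)
  }
  list(dispensations = disp, true_index = true_index, first_aed = first_aed)
}

sim_deaths <- function(params, ins, flags, true_index) {
  n <- params$n_insurants
  death <- rep(as.Date(NA), n)
  # background: exponential from entry into the window (enrollment start)
  bg <- !flags$is_refr
  if (params$background_hazard > 0) {
    t_bg <- stats::rexp(sum(bg), params$background_hazard) * 365
    d_bg <- ins$enroll_start[bg] + round(t_bg)
    d_bg[d_bg > params$observation_end] <- NA
    death[bg] <- d_bg
  }
  # cases: piecewise hazard from index (higher in the first follow-up year)
  ci <- which(flags$is_refr)
  if (length(ci)) {
    h1 <- params$case_hazard_year1; h2 <- params$case_hazard_later
    e <- stats::rexp(length(ci))
    t_yr <- ifelse(e < h1, e / h1, 1 + (e - h1) / ifelse(h2 > 0, h2, Inf))
    d <- true_index[ci] + round(t_yr * 365)
    d[d > params$observation_end] <- NA
    death[ci] <- d
  }
  death
}

sim_epilepsy_diagnoses <- function(params, ins, flags, first_aed,
                                   end_of_follow) {
  idx <- which(flags$has_ep)
  if (!length(idx)) return(NULL)
  rows <- list()
  codes <- c("G40.2", "G40.3", "G40.9")
  for (i in idx) {
    from <- if (!is.na(first_aed[i])) first_aed[i] else ins$enroll_start[i]
    from <- max(from, ins$enroll_start[i])
    to <- end_of_follow[i]
    if (to < from) to <- from
    qs <- unique(quarter_of(seq(from, to, by = "3 months")))
    hit <- stats::runif(length(qs)) < 0.6
    hit[1] <- TRUE  # a coded diagnosis always exists
    qs <- qs[hit]
    rows[[length(rows) + 1]] <- data.frame(
      insurant_id = ins$insurant_id[i], quarter = qs,
      icd_code = sample(codes, length(qs), replace = TRUE),
      setting = "outpatient", position = "primary", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

sim_comorbidities <- function(params, ins, flags, end_of_follow) {
  com <- params$comorbidity_profile
  years <- seq(as.integer(format(params$observation_start, "%Y")),
               as.integer(format(params$observation_end, "%Y")))
  n <- nrow(ins)
  out <- list()
  p_person <- ifelse(flags$is_refr, 1, 0)
  for (b in seq_len(nrow(com))) {
    p <- ifelse(flags$is_refr, com$p_case[b], com$p_control[b])
    for (y in years) {
      hit <- stats::runif(n) < p
      if (!any(hit)) next
      q <- sprintf("%dQ%d", y, sample.int(4, sum(hit), replace = TRUE))
      out[[length(out) + 1]] <- data.frame(
        insurant_id = ins$insurant_id[hit], quarter = q,
        icd_code = com$icd_code[b], setting = "outpatient",
        position = "secondary", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  dg <- do.call(rbind, out)
  # drop records after death/disenrollment or before enrollment
  m <- match(dg$insurant_id, ins$insurant_id)
  qs <- quarter_start(dg$quarter)
  dg[qs <= end_of_follow[m] & qs >= ins$enroll_start[m], , drop = FALSE]
}

.nonepilepsy_primaries <- c("I63.9", "J18.9", "K35.8", "F32.1", "T14.0",
                            "S06.0", "M54.5", "I20.0", "K21.0", "E11.9")

sim_admissions <- function(params, ins, flags, end_of_follow) {
  n <- nrow(ins)
  start <- pmax(ins$enroll_start, params$observation_start)
  exp_days <- pmax(as.numeric(end_of_follow - start) + 1, 0)
  rate <- ifelse(flags$is_refr, params$admission_rate_case,
                 params$admission_rate_control)
  shape <- ifelse(flags$is_refr, params$admission_dispersion_case,
                  params$admission_dispersion_control)
  frailty <- ifelse(is.finite(shape),
                    stats::rgamma(n, shape = pmin(shape, 1e6),
                                  rate = pmin(shape, 1e6)), 1)
  n_adm <- stats::rpois(n, rate * frailty * exp_days / 365)
  tot <- sum(n_adm)
  if (tot == 0)
    return(list(admissions = data.frame(
      insurant_id = character(), admit_date = as.Date(character()),
      discharge_date = as.Date(character()), primary_icd = character(),
      secondary_icds = character(), ops_codes = character(),
      drg_cost = numeric(), stringsAsFactors = FALSE)))
  who <- rep(seq_len(n), n_adm)
  admit <- start[who] + floor(stats::runif(tot) * pmax(exp_days[who], 1))
  admit <- as.Date(pmin(as.numeric(admit), as.numeric(end_of_follow[who])),
                   origin = "1970-01-01")
  los <- pmax(1, round(stats::rlnorm(tot, params$los_meanlog,
                                     params$los_sdlog)))
  discharge <- admit + los - 1
  lim <- pmin(as.numeric(end_of_follow[who]),
              as.numeric(params$observation_end))
  discharge <- as.Date(pmin(as.numeric(discharge), lim),
                       origin = "1970-01-01")

  is_case <- flags$is_refr[who]
  epi <- is_case & stats::runif(tot) < params$epilepsy_admission_fraction
  se <- epi & stats::runif(tot) < params$status_epilepticus_fraction
  primary <- sample(.nonepilepsy_primaries, tot, replace = TRUE)
  primary[epi] <- sample(c("G40.2", "G40.3", "G40.9"), sum(epi),
                         replace = TRUE)
  primary[se] <- "G41.0"

  ops <- character(tot)
  if (any(epi)) {
    ei <- which(epi)
    add <- function(code, p) {
      pick <- ei[stats::runif(length(ei)) < p]
      ops[pick] <<- ifelse(nzchar(ops[pick]), paste(ops[pick], code,
                                                    sep = ";"), code)
    }
    add("8-972.2", params$ops_complex_prob)
    add("1-210", params$ops_video_eeg_prob)
    add("5-010", params$ops_surgery_prob)
  }
  sec <- character(tot)
  sec[is_case & !epi] <- "G40.9"

  adm <- data.frame(insurant_id = ins$insurant_id[who], admit_date = admit,
                    discharge_date = discharge, primary_icd = primary,
                    secondary_icds = sec, ops_codes = ops,
                    drg_cost = round(stats::rlnorm(tot,
                                                   params$drg_cost_meanlog,
                                                   params$drg_cost_sdlog), 2),
                    stringsAsFactors = FALSE)
  adm <- adm[order(adm$insurant_id, adm$admit_date), , drop = FALSE]
  rownames(adm) <- NULL
  list(admissions = adm)
}

# share of insurant-years with any contact and mean annual contacts, by
# specialty, for the case and control profiles
.contact_profiles <- list(
  case = data.frame(
    specialty = c("general_practitioner", "neurologist", "neuropsychiatrist",
                  "neuropediatrician", "radiologist", "other"),
    share = c(0.95, 0.30, 0.40, 0.03, 0.21, 0.50),
    visits = c(5.0, 2.9, 3.4, 2.1, 1.3, 2.0),
    prescriber = c(0.55, 0.60, 0.60, 0.50, 0, 0),
    child_only = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE),
  control = data.frame(
    specialty = c("general_practitioner", "neurologist", "neuropsychiatrist",
                  "neuropediatrician", "radiologist", "other"),
    share = c(0.75, 0.03, 0.05, 0.01, 0.10, 0.40),
    visits = c(3.2, 1.5, 2.0, 1.5, 1.2, 1.5),
    prescriber = c(0, 0, 0, 0, 0, 0),
    child_only = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE))

# annual non-physician cost components (ancillary remedies, special
# equipment, dialysis), probability and lognormal size by cohort
.extra_costs <- data.frame(
  component = c("ancillary_cost", "equipment_cost", "dialysis_cost"),
  p_case = c(0.60, 0.15, 0.010),
  meanlog_case = log(c(2200, 2000, 15000)),
  p_control = c(0.20, 0.05, 0.005),
  meanlog_control = log(c(800, 1000, 15000)),
  sdlog = c(0.5, 0.6, 0.3),
  stringsAsFactors = FALSE)

sim_outpatient <- function(params, ins, flags, end_of_follow) {
  years <- seq(as.integer(format(params$observation_start, "%Y")),
               as.integer(format(params$observation_end, "%Y")))
  n <- nrow(ins)
  ref_year <- as.integer(format(params$observation_start, "%Y")) + 2L
  is_child <- (ref_year - ins$birth_year) < 18
  out <- list()
  for (grp in c("case", "control")) {
    gi <- if (grp == "case") which(flags$is_refr) else which(!flags$is_refr)
    if (!length(gi)) next
    prof <- .contact_profiles[[grp]]
    for (s in seq_len(nrow(prof))) {
      share <- prof$share[s]
      elig <- if (prof$child_only[s]) gi[is_child[gi]] else gi
      if (!length(elig)) next
      for (y in years) {
        hit <- elig[stats::runif(length(elig)) < share]
        if (!length(hit)) next
        visits <- 1L + stats::rpois(length(hit), max(prof$visits[s] - 1, 0))
        q <- sample.int(4, length(hit), replace = TRUE)
        presc <- stats::runif(length(hit)) < prof$prescriber[s]
        cost <- round(visits * stats::rlnorm(length(hit),
                                             params$contact_cost_meanlog,
                                             params$contact_cost_sdlog), 2)
        out[[length(out) + 1]] <- data.frame(
          insurant_id = ins$insurant_id[hit],
          quarter = sprintf("%dQ%d", y, q),
          specialty = prof$specialty[s], n_contacts = visits,
          prescriber_of_aed = presc, cost = cost,
          ancillary_cost = 0, equipment_cost = 0, dialysis_cost = 0,
          stringsAsFactors = FALSE)
      }
    }
    # annual extras carried on a dedicated "other" row
    for (b in seq_len(nrow(.extra_costs))) {
      p <- if (grp == "case") .extra_costs$p_case[b] else
        .extra_costs$p_control[b]
      ml <- if (grp == "case") .extra_costs$meanlog_case[b] else
        .extra_costs$meanlog_control[b]
      for (y in years) {
        hit <- gi[stats::runif(length(gi)) < p]
        if (!length(hit)) next
        amt <- round(stats::rlnorm(length(hit), ml, .extra_costs$sdlog[b]), 2)
        row <- data.frame(
          insurant_id = ins$insurant_id[hit],
          quarter = sprintf("%dQ%d", y, sample.int(4, length(hit),
                                                   replace = TRUE)),
          specialty = "other", n_contacts = 1L, prescriber_of_aed = FALSE,
          cost = 0, ancillary_cost = 0, equipment_cost = 0, dialysis_cost = 0,
          stringsAsFactors = FALSE)
        row[[.extra_costs$component[b]]] <- amt
        out[[length(out) + 1]] <- row
      }
    }
  }
  if (!length(out)) return(NULL)
  op <- do.call(rbind, out)
  m <- match(op$insurant_id, ins$insurant_id)
  qs <- quarter_start(op$quarter)
  op <- op[qs <= end_of_follow[m] & qs >= ins$enroll_start[m], , drop = FALSE]
  op <- op[order(op$insurant_id, op$quarter, op$specialty), , drop = FALSE]
  rownames(op) <- NULL
  op
}
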