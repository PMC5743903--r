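# Top-level analysis: phenotype -> match -> burden -> survival, returned as
# a classed object with print/summary methods, in the style of a fitted
# model. run_pipeline() wraps it with file input/output and a
# reproducibility manifest.

#' Run the full SDRE cohort study on a claims database
#'
#' Identifies SDRE cases, draws the age/sex-matched epilepsy-free
#' comparison cohort, and computes every descriptive outcome: demographics
#' at index, all-cause and epilepsy-specific hospitalization, procedure
#' uptake, status-epilepticus admissions, prescription patterns,
#' per-code-set comorbidity prevalence with chi-square tests,
#' Kaplan-Meier survival from index (cases) and pseudo-index (controls)
#' with the cumulative three-year mortality read-off, and direct costs.
#'
#' @param db a [claims_db()].
#' @param config a [phenotype_config()].
#' @param ratio target controls per case.
#' @param seed seed for control sampling.
#' @param code_sets named list of [code_set()]s for prevalence comparisons.
#' @param cost_mode `"index_anchored"` or `"calendar"` (see
#'   [cost_summary()]).
#' @param ops_prefixes OPS procedure prefixes to report.
#' @param prevalence_period period for the comorbidity comparison (default
#'   first follow-up year).
#' @return object of class `sdre_study`.
#' @export
sdre_study <- function(db, config = phenotype_config(), ratio = 20L,
                       seed = 1L, code_sets = default_code_sets(),
                       cost_mode = "index_anchored",
                       ops_prefixes = c("8-972", "1-210", "5-010"),
                       prevalence_period = "fu1") {
  stopifnot(inherits(db, "claims_db"))
  cases <- identify_sdre_cases(db, config)
  matched <- match_controls(db, cases, ratio = ratio, seed = seed,
                            epilepsy_icd_prefix = config$epilepsy_icd_prefix)
  case_cohort <- cases[, c("insurant_id", "index_date")]
  ctrl_cohort <- control_cohort(matched)

  demo <- NULL
  if (nrow(cases)) {
    ins <- db$insurants[match(cases$insurant_id, db$insurants$insurant_id), ]
    age <- as.integer(format(cases$index_date, "%Y")) - ins$birth_year
    demo <- list(n = nrow(cases), mean_age = mean(age), sd_age = stats::sd(age),
                 pct_female = 100 * mean(ins$sex == "female"),
                 pct_male = 100 * mean(ins$sex == "male"),
                 pct_children = 100 * mean(age < 18),
                 pct_over65 = 100 * mean(age > 65))
  }

  empty <- nrow(cases) == 0
  burden <- prescriptions <- contacts <- prevalence <- costs <- NULL
  survival <- mortality <- status_epi <- NULL
  if (!empty) {
    burden <- rbind(
      hospitalization_summary(db, case_cohort, cohort_label = "sdre",
                              config = config),
      hospitalization_summary(db, case_cohort, epilepsy_specific = TRUE,
                              cohort_label = "sdre", config = config),
      procedure_uptake(db, case_cohort, ops_prefixes = ops_prefixes,
                       cohort_label = "sdre", config = config))
    if (nrow(ctrl_cohort))
      burden <- rbind(burden,
                      hospitalization_summary(db, ctrl_cohort,
                                              cohort_label = "control",
                                              config = config))
    status_epi <- status_epilepticus_hospitalized(db, case_cohort,
                                                  config = config)
    prescriptions <- prescription_pattern(db, case_cohort,
                                          atc_prefix = config$aed_atc_prefix,
                                          config = config)
    contacts <- rbind(
      contact_summary(db, case_cohort, cohort_label = "sdre",
                      config = config),
      if (nrow(ctrl_cohort))
        contact_summary(db, ctrl_cohort, cohort_label = "control",
                        config = config))
    if (nrow(ctrl_cohort)) {
      prevalence <- do.call(rbind, lapply(names(code_sets), function(nm) {
        pc <- prevalence_compare(db, case_cohort, ctrl_cohort,
                                 code_sets[[nm]],
                                 period = prevalence_period, config = config)
        data.frame(code_set = nm, p_case = pc$p_case,
                   p_control = pc$p_control, n_case = pc$n_case,
                   n_control = pc$n_control, denom_case = pc$denom_case,
                   denom_control = pc$denom_control,
                   statistic = pc$statistic, p_value = pc$p_value,
                   stringsAsFactors = FALSE)
      }))
    }
    # control costs are computed for completeness but are not comparable to
    # case costs (no published control cost breakdown exists)
    costs <- rbind(
      cost_summary(db, case_cohort, mode = cost_mode,
                   cohort_label = "sdre", config = config),
      if (nrow(ctrl_cohort))
        cost_summary(db, ctrl_cohort, mode = cost_mode,
                     cohort_label = "control", config = config))

    survival <- list(
      sdre = cohort_survival(db, case_cohort, config),
      control = if (nrow(ctrl_cohort)) cohort_survival(db, ctrl_cohort,
                                                       config))
    horizon <- 365 * config$followup_years
    mortality <- list(
      sdre_3yr = cumulative_mortality(survival$sdre, horizon),
      control_3yr = if (!is.null(survival$control))
        cumulative_mortality(survival$control, horizon))
  }
  structure(list(cases = cases, matched = matched, demographics = demo,
                 burden = burden, status_epilepticus = status_epi,
                 prescriptions = prescriptions, contacts = contacts,
                 prevalence = prevalence, costs = costs, survival = survival,
                 mortality = mortality, config = config, ratio = ratio,
                 seed = seed, cost_mode = cost_mode),
            class = "sdre_study")
}

# Follow-up duration and death indicator from (pseudo-)index to death or
# censoring at disenrollment / end of observation. Same-day deaths get a
# half-day duration so the product-limit estimator sees a positive time.
cohort_survival <- function(db, cohort, config = phenotype_config()) {
  ins <- db$insurants[match(cohort$insurant_id, db$insurants$insurant_id), ]
  end <- pmin(ins$enroll_end, db$observation_end)
  death <- ins$death_date
  observed <- !is.na(death) & death <= end
  stop_date <- as.Date(ifelse(observed, as.numeric(death), as.numeric(end)),
                       origin = "1970-01-01")
  dur <- pmax(as.numeric(stop_date - cohort$index_date), 0.5)
  km_curve(dur, observed)
}

#' @export
print.sdre_study <- function(x, ...) {
  cat("SDRE claims cohort study\n")
  cat("  cases identified:   ", nrow(x$cases), "\n")
  cat("  matched controls:   ", nrow(x$matched$pairs),
      sprintf("(target ratio %d:1)\n", x$ratio))
  if (!is.null(x$demographics))
    cat(sprintf("  mean age %.1f, %.1f%% female, %.1f%% under 18\n",
                x$demographics$mean_age, x$demographics$pct_female,
                x$demographics$pct_children))
  if (!is.null(x$mortality)) {
    cat(sprintf("  3-year mortality:    %.1f%% (cases)",
                100 * x$mortality$sdre_3yr))
    if (!is.null(x$mortality$control_3yr))
      cat(sprintf(" vs %.1f%% (controls)", 100 * x$mortality$control_3yr))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.sdre_study <- function(object, ...) {
  structure(list(study = object), class = "summary.sdre_study")
}

#' @export
print.summary.sdre_study <- function(x, ...) {
  s <- x$study
  print(s)
  b <- s$burden
  if (!is.null(b)) {
    hp <- b[b$metric == "hospitalized_prop", ]
    cat("\nAnnual hospitalization (share with >=1 admission):\n")
    for (i in seq_len(nrow(hp)))
      cat(sprintf("  %-8s %-8s %5.1f%% (%d/%d)\n", hp$cohort[i],
                  hp$period[i], 100 * hp$value[i], hp$numerator[i],
                  hp$denominator[i]))
  }
  if (!is.null(s$prescriptions))
    cat(sprintf("\nDistinct anticonvulsants over follow-up: mean %.1f (SD %.1f)\n",
                s$prescriptions$distinct$mean, s$prescriptions$distinct$sd))
  if (!is.null(s$prevalence)) {
    cat("\nComorbidity prevalence, first follow-up year (case vs control):\n")
    p <- s$prevalence
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %-22s %5.1f%% vs %5.1f%%  (p %s)\n", p$code_set[i],
                  100 * p$p_case[i], 100 * p$p_control[i],
                  format_p(p$p_value[i])))
  }
  if (!is.null(s$costs)) {
    cc <- s$costs[s$costs$cohort == "sdre", ]
    cat("\nDirect costs per person-year (cases):\n")
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %-8s EUR %9.0f\n", cc$period[i],
                  cc$total_per_person_year[i]))
  }
  invisible(x)
}

# p-value formatting in report style: three significant digits, "<0.001"
# below that
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", paste0("= ", signif(p, 3)))
}
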