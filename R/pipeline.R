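# One-command pipeline: simulate or load claims, validate, run the study,
# and write paper-shaped report tables plus a reproducibility manifest.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate synthetic claims) or `"load"` (read a
#'   claims directory written by [write_claims()]).
#' @param out_dir report output directory.
#' @param claims_dir input directory, required in load mode.
#' @param sim a [sim_params()] object for simulate mode; its seed is
#'   overridden by `seed` so one value controls the whole run.
#' @param phenotype a [phenotype_config()].
#' @param ratio controls per case.
#' @param seed master seed, recorded in the manifest.
#' @param code_sets_file optional code-set config for [read_code_sets()];
#'   defaults to the built-in sets.
#' @param cost_mode `"index_anchored"` or `"calendar"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), out_dir,
                            claims_dir = NULL,
                            sim = default_params("small"),
                            phenotype = phenotype_config(), ratio = 20L,
                            seed = 11L, code_sets_file = NULL,
                            cost_mode = "index_anchored") {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(claims_dir) || !dir.exists(claims_dir))
      stopf("load mode requires an existing claims_dir")
  }
  if (!is.null(code_sets_file) && !file.exists(code_sets_file))
    stopf("code_sets_file '%s' does not exist", code_sets_file)
  structure(list(mode = mode, out_dir = out_dir, claims_dir = claims_dir,
                 sim = sim, phenotype = phenotype, ratio = as.integer(ratio),
                 seed = as.integer(seed), code_sets_file = code_sets_file,
                 cost_mode = cost_mode),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the end-to-end pipeline and write report tables
#'
#' Simulates or loads a claims database, validates it (any structural
#' violation aborts the run), executes [sdre_study()], and writes
#' `cases.csv`, `matched.csv`, `burden_table.csv`, `costs.csv`,
#' `prescriptions.csv`, `survival_sdre.csv`, `survival_control.csv` and
#' `manifest.json` (configuration, seeds, package version and row counts,
#' so that identical inputs reproduce identical outputs) to the output
#' directory; simulate mode additionally writes `ground_truth.csv`. Stage
#' progress and row counts are logged via `message()` so filter attrition
#' is auditable.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `out_dir` and the fitted `study`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (config$mode == "simulate") {
    sim <- config$sim
    sim$seed <- config$seed
    res <- run_stage("simulate", simulate_claims(sim))
    db <- res$db
    truth <- res$truth
  } else {
    db <- run_stage("load", load_claims(config$claims_dir))
  }
  message(sprintf("[input] %d insurants, %d dispensations, %d admissions",
                  nrow(db$insurants), nrow(db$dispensations),
                  nrow(db$admissions)))
  viol <- run_stage("validate", validate_claims(db))
  if (nrow(viol) > 0)
    run_stage("validate",
              stopf("%d structural violation(s); first: %s row %d: %s",
                    nrow(viol), viol$table[1], viol$row[1], viol$rule[1]))
  code_sets <- if (is.null(config$code_sets_file)) default_code_sets() else
    run_stage("code_sets", read_code_sets(config$code_sets_file))
  study <- run_stage("study",
                     sdre_study(db, config = config$phenotype,
                                ratio = config$ratio, seed = config$seed,
                                code_sets = code_sets,
                                cost_mode = config$cost_mode))
  message(sprintf("[phenotype] %d cases; [match] %d controls",
                  nrow(study$cases), nrow(study$matched$pairs)))

  out <- config$out_dir
  wcsv <- function(x, name) {
    if (is.null(x)) x <- data.frame()
    for (col in names(x)) if (inherits(x[[col]], "Date"))
      x[[col]] <- format(x[[col]], "%Y-%m-%d")
    utils::write.csv(x, file.path(out, name), row.names = FALSE)
  }
  run_stage("write", {
    wcsv(as.data.frame(study$cases)[, c("insurant_id", "index_date",
                                        "n_qualifying_substances",
                                        "substances")], "cases.csv")
    m <- merge(study$matched$pairs, study$matched$pseudo_index,
               by = "control_id")[, c("case_id", "control_id",
                                      "pseudo_index")]
    m <- m[order(m$case_id, m$control_id), ]
    wcsv(m, "matched.csv")
    wcsv(study$burden, "burden_table.csv")
    wcsv(study$costs, "costs.csv")
    wcsv(if (is.null(study$prescriptions)) NULL else
      study$prescriptions$shares, "prescriptions.csv")
    wcsv(if (is.null(study$survival$sdre)) NULL else
      as.data.frame(study$survival$sdre), "survival_sdre.csv")
    wcsv(if (is.null(study$survival$control)) NULL else
      as.data.frame(study$survival$control), "survival_control.csv")
    if (!is.null(truth)) wcsv(truth, "ground_truth.csv")
    manifest <- list(
      package = "sdreburden",
      version = as.character(utils::packageVersion("sdreburden")),
      mode = config$mode, seed = config$seed, ratio = config$ratio,
      cost_mode = config$cost_mode,
      phenotype = unclass(config$phenotype)[
        c("epilepsy_icd_prefix", "aed_atc_prefix", "k_distinct",
          "window_days")],
      sim = if (config$mode == "simulate") list(
        n_insurants = config$sim$n_insurants,
        epilepsy_prevalence = config$sim$epilepsy_prevalence,
        refractory_fraction = config$sim$refractory_fraction) else NULL,
      claims_dir = config$claims_dir,
      rows_in = lapply(CLAIMS_TABLES, function(tb) nrow(db[[tb]])),
      n_cases = nrow(study$cases),
      n_controls = nrow(study$matched$pairs))
    names(manifest$rows_in) <- CLAIMS_TABLES
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })
  invisible(list(out_dir = out, study = study))
}

#' Print a plain-text summary of a pipeline report directory
#'
#' Reads the report tables written by [run_pipeline()] and prints the
#' headline numbers (cohort size, hospitalization, mortality, costs). A
#' missing table is fatal and names the file.
#'
#' @param report_dir directory written by [run_pipeline()].
#' @return invisibly, the printed lines.
#' @export
render_summary <- function(report_dir) {
  need <- c("cases.csv", "matched.csv", "burden_table.csv", "costs.csv",
            "prescriptions.csv", "survival_sdre.csv", "survival_control.csv")
  for (f in need)
    if (!file.exists(file.path(report_dir, f)))
      stopf("missing report table '%s'", f)
  rd <- function(f) {
    x <- tryCatch(utils::read.csv(file.path(report_dir, f),
                                  stringsAsFactors = FALSE),
                  error = function(e) data.frame())
    x
  }
  cases <- rd("cases.csv")
  matched <- rd("matched.csv")
  lines <- character()
  say <- function(...) lines <<- c(lines, sprintf(...))
  say("%d cases identified", nrow(cases))
  say("%d matched controls", nrow(matched))
  burden <- rd("burden_table.csv")
  if (nrow(burden)) {
    hp <- burden[burden$metric == "hospitalized_prop" &
                   burden$period == "fu1", ]
    for (i in seq_len(nrow(hp)))
      say("hospitalized in follow-up year 1 (%s): %.1f%%", hp$cohort[i],
          100 * hp$value[i])
  }
  mort <- function(f, label) {
    sv <- rd(f)
    if (nrow(sv)) {
      at <- sv[sv$time <= 3 * 365, ]
      s <- if (nrow(at)) at$survival[nrow(at)] else 1
      say("3-year mortality (%s): %.1f%%", label, 100 * (1 - s))
    }
  }
  mort("survival_sdre.csv", "cases")
  mort("survival_control.csv", "controls")
  costs <- rd("costs.csv")
  if (nrow(costs)) {
    cc <- costs[costs$cohort == "sdre" & costs$period %in%
                  c("fu1", "fu2", "fu3"), ]
    for (i in seq_len(nrow(cc)))
      say("direct costs per person-year, %s: EUR %.0f", cc$period[i],
          cc$total_per_person_year[i])
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
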