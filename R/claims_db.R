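# Claims data model: typed longitudinal claims tables, delimited-file
# readers/writers and structural validation.
#
# The container mirrors the structure of German statutory health-insurance
# (GKV) research databases: an insurant master table plus four child tables
# (outpatient diagnoses by calendar quarter, drug dispensations with ATC code
# and day-level date, inpatient admissions with ICD/OPS codes and G-DRG cost,
# and outpatient physician contacts by quarter and specialty).

CLAIMS_TABLES <- c("insurants", "diagnoses", "dispensations", "admissions",
                   "outpatient")

.icd_pattern <- "^[A-Z][0-9]{2}(\\.[0-9]+)?$"
.atc_pattern <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
.ops_pattern <- "^[0-9]-[0-9]{2,3}(\\.[0-9a-z]+)?$"

empty_claims_tables <- function() {
  list(
    insurants = data.frame(insurant_id = character(), birth_year = integer(),
                           sex = character(), enroll_start = as.Date(character()),
                           enroll_end = as.Date(character()),
                           death_date = as.Date(character()),
                           stringsAsFactors = FALSE),
    diagnoses = data.frame(insurant_id = character(), quarter = character(),
                           icd_code = character(), setting = character(),
                           position = character(), stringsAsFactors = FALSE),
    dispensations = data.frame(insurant_id = character(),
                               dispense_date = as.Date(character()),
                               atc_code = character(),
                               substance_name = character(),
                               cost = numeric(), stringsAsFactors = FALSE),
    admissions = data.frame(insurant_id = character(),
                            admit_date = as.Date(character()),
                            discharge_date = as.Date(character()),
                            primary_icd = character(),
                            secondary_icds = character(),
                            ops_codes = character(), drg_cost = numeric(),
                            stringsAsFactors = FALSE),
    outpatient = data.frame(insurant_id = character(), quarter = character(),
                            specialty = character(), n_contacts = integer(),
                            prescriber_of_aed = logical(), cost = numeric(),
                            ancillary_cost = numeric(),
                            equipment_cost = numeric(),
                            dialysis_cost = numeric(),
                            stringsAsFactors = FALSE)
  )
}

#' Construct a claims database
#'
#' Bundles the five claims tables and the observation window into a
#' `claims_db` object. Tables are type-coerced to the documented column
#' layouts; missing optional columns (dispensation `cost`, outpatient
#' ancillary/equipment/dialysis cost components) are filled with zeros.
#' Construction does not validate content — run [validate_claims()] for the
#' full structural rule set.
#'
#' @param insurants data frame with columns `insurant_id`, `birth_year`,
#'   `sex` (`"female"`/`"male"`), `enroll_start`, `enroll_end`, `death_date`
#'   (NA when alive).
#' @param diagnoses data frame with `insurant_id`, `quarter` (`"YYYYQn"`),
#'   `icd_code` (ICD-10-GM), `setting` (`"inpatient"`/`"outpatient"`),
#'   `position` (`"primary"`/`"secondary"`).
#' @param dispensations data frame with `insurant_id`, `dispense_date`,
#'   `atc_code` (7-character substance level), `substance_name`, and optional
#'   `cost` in EUR.
#' @param admissions data frame with `insurant_id`, `admit_date`,
#'   `discharge_date`, `primary_icd`, `secondary_icds` and `ops_codes`
#'   (semicolon-joined lists), `drg_cost` in EUR.
#' @param outpatient data frame with `insurant_id`, `quarter`, `specialty`,
#'   `n_contacts`, `prescriber_of_aed`, `cost`, and optional
#'   `ancillary_cost`, `equipment_cost`, `dialysis_cost`.
#' @param observation_start,observation_end dates bounding the observation
#'   window (default 2008-01-01 to 2013-12-31, i.e. 24 billing quarters).
#' @return An object of class `claims_db`: a list of the five tables plus
#'   `observation_start` and `observation_end`.
#' @seealso [validate_claims()], [write_claims()], [load_claims()]
#' @export
#' @examples
#' db <- claims_db(insurants = data.frame(
#'   insurant_id = "i1", birth_year = 1980L, sex = "female",
#'   enroll_start = as.Date("2008-01-01"), enroll_end = as.Date("2013-12-31"),
#'   death_date = as.Date(NA)))
#' nrow(db$insurants)
claims_db <- function(insurants = NULL, diagnoses = NULL, dispensations = NULL,
                      admissions = NULL, outpatient = NULL,
                      observation_start = as.Date("2008-01-01"),
                      observation_end = as.Date("2013-12-31")) {
  tpl <- empty_claims_tables()
  coerce <- function(x, template, name) {
    if (is.null(x) || nrow(x) == 0) return(template)
    for (col in names(template)) {
      if (!col %in% names(x)) {
        if (col %in% c("cost", "ancillary_cost", "equipment_cost",
                       "dialysis_cost", "drg_cost")) {
          x[[col]] <- 0
        } else if (col == "death_date") {
          x[[col]] <- as.Date(NA)
        } else if (col %in% c("secondary_icds", "ops_codes")) {
          x[[col]] <- ""
        } else {
          stopf("table '%s' is missing required column '%s'", name, col)
        }
      }
      x[[col]] <- switch(class(template[[col]])[1],
        Date = as.Date(x[[col]]),
        integer = as.integer(x[[col]]),
        numeric = as.numeric(x[[col]]),
        logical = as.logical(x[[col]]),
        as.character(x[[col]]))
    }
    x <- x[names(template)]
    rownames(x) <- NULL
    x
  }
  db <- structure(list(
    insurants = coerce(insurants, tpl$insurants, "insurants"),
    diagnoses = coerce(diagnoses, tpl$diagnoses, "diagnoses"),
    dispensations = coerce(dispensations, tpl$dispensations, "dispensations"),
    admissions = coerce(admissions, tpl$admissions, "admissions"),
    outpatient = coerce(outpatient, tpl$outpatient, "outpatient"),
    observation_start = as.Date(observation_start),
    observation_end = as.Date(observation_end)
  ), class = "claims_db")
  db
}

#' @export
print.claims_db <- function(x, ...) {
  cat("<claims_db> observation window", format(x$observation_start), "to",
      format(x$observation_end), "\n")
  for (tb in CLAIMS_TABLES)
    cat(sprintf("  %-14s %8d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' Validate a claims database
#'
#' Checks every structural invariant of the claims model and returns the
#' violations as data, not exceptions: each row names the table, the row
#' index and the rule broken. An empty result means the database is
#' structurally sound.
#'
#' Rules cover date ordering (enrollment, admission/discharge, death within
#' enrollment), code syntax (ICD-10-GM, 7-character ATC, OPS), containment of
#' all dates and quarters in the observation window, non-negative costs and
#' contact counts, and referential integrity of `insurant_id` against the
#' insurant master table.
#'
#' @param db a [claims_db()] object.
#' @return data frame with columns `table`, `row`, `rule`, `detail`;
#'   zero rows when valid.
#' @export
validate_claims <- function(db) {
  stopifnot(inherits(db, "claims_db"))
  v <- list()
  add <- function(table, rows, rule, detail = "") {
    rows <- which(rows)
    if (length(rows))
      v[[length(v) + 1]] <<- data.frame(table = table, row = rows, rule = rule,
                                        detail = detail,
                                        stringsAsFactors = FALSE)
  }
  ins <- db$insurants
  ids <- ins$insurant_id
  os <- db$observation_start; oe <- db$observation_end

  add("insurants", duplicated(ids), "unique insurant_id")
  add("insurants", !ins$sex %in% c("female", "male"), "sex in {female,male}")
  add("insurants", !is.na(ins$enroll_start) & !is.na(ins$enroll_end) &
        ins$enroll_start > ins$enroll_end, "enroll_start<=enroll_end")
  add("insurants", !is.na(ins$birth_year) &
        ins$birth_year > as.integer(format(ins$enroll_start, "%Y")),
      "birth_year<=year(enroll_start)")
  add("insurants", !is.na(ins$death_date) &
        (ins$death_date < ins$enroll_start | ins$death_date > ins$enroll_end),
      "death within enrollment")

  dg <- db$diagnoses
  add("diagnoses", !dg$insurant_id %in% ids, "foreign key")
  add("diagnoses", !quarter_ok(dg$quarter), "quarter format YYYYQn")
  qok <- quarter_ok(dg$quarter)
  if (any(qok))
    add("diagnoses", qok & (quarter_start(ifelse(qok, dg$quarter, "2008Q1")) < os |
          quarter_end(ifelse(qok, dg$quarter, "2008Q1")) > oe),
        "quarter within observation window")
  add("diagnoses", !grepl(.icd_pattern, toupper(dg$icd_code)), "ICD pattern")
  add("diagnoses", !dg$setting %in% c("inpatient", "outpatient"),
      "setting in {inpatient,outpatient}")
  add("diagnoses", !dg$position %in% c("primary", "secondary"),
      "position in {primary,secondary}")

  dp <- db$dispensations
  add("dispensations", !dp$insurant_id %in% ids, "foreign key")
  add("dispensations", is.na(dp$dispense_date), "parsable dispense_date")
  add("dispensations", !is.na(dp$dispense_date) &
        (dp$dispense_date < os | dp$dispense_date > oe),
      "dispense_date within observation window")
  add("dispensations", !grepl(.atc_pattern, toupper(dp$atc_code)),
      "ATC 7-character substance code")
  add("dispensations", !is.na(dp$cost) & dp$cost < 0, "cost>=0")

  ad <- db$admissions
  add("admissions", !ad$insurant_id %in% ids, "foreign key")
  add("admissions", !is.na(ad$admit_date) & !is.na(ad$discharge_date) &
        ad$admit_date > ad$discharge_date, "admit<=discharge")
  add("admissions", !is.na(ad$admit_date) & (ad$admit_date < os | ad$admit_date > oe),
      "admit_date within observation window")
  add("admissions", !is.na(ad$discharge_date) & ad$discharge_date > oe,
      "discharge_date within observation window")
  add("admissions", !grepl(.icd_pattern, toupper(ad$primary_icd)),
      "primary ICD pattern")
  add("admissions", !is.na(ad$drg_cost) & ad$drg_cost < 0, "drg_cost>=0")
  bad_sec <- vapply(strsplit(ad$secondary_icds, ";", fixed = TRUE),
                    function(x) {
                      x <- trimws(x[nzchar(trimws(x))])
                      length(x) > 0 && !all(grepl(.icd_pattern, toupper(x)))
                    }, logical(1))
  add("admissions", bad_sec, "secondary ICD pattern")
  bad_ops <- vapply(strsplit(ad$ops_codes, ";", fixed = TRUE),
                    function(x) {
                      x <- trimws(x[nzchar(trimws(x))])
                      length(x) > 0 && !all(grepl(.ops_pattern, x))
                    }, logical(1))
  add("admissions", bad_ops, "OPS pattern")

  op <- db$outpatient
  add("outpatient", !op$insurant_id %in% ids, "foreign key")
  add("outpatient", !quarter_ok(op$quarter), "quarter format YYYYQn")
  qok <- quarter_ok(op$quarter)
  if (any(qok))
    add("outpatient", qok & (quarter_start(ifelse(qok, op$quarter, "2008Q1")) < os |
          quarter_end(ifelse(qok, op$quarter, "2008Q1")) > oe),
        "quarter within observation window")
  add("outpatient", !is.na(op$n_contacts) & op$n_contacts < 1, "n_contacts>=1")
  for (cc in c("cost", "ancillary_cost", "equipment_cost", "dialysis_cost"))
    add("outpatient", !is.na(op[[cc]]) & op[[cc]] < 0, paste0(cc, ">=0"))

  if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), row = integer(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
}

#' Write a claims database to delimited files
#'
#' Writes the five claims tables as UTF-8, comma-delimited CSV files with a
#' header row (`insurants.csv`, `diagnoses.csv`, `dispensations.csv`,
#' `admissions.csv`, `outpatient.csv`), plus `observation.csv` holding the
#' observation window. Dates are ISO-8601; list-valued fields
#' (`secondary_icds`, `ops_codes`) are semicolon-joined. [load_claims()] on
#' the output reproduces the database field-for-field.
#'
#' @param db a [claims_db()] object.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_claims <- function(db, dir_path) {
  stopifnot(inherits(db, "claims_db"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (tb in CLAIMS_TABLES) {
    x <- db[[tb]]
    for (col in names(x)) if (inherits(x[[col]], "Date"))
      x[[col]] <- format(x[[col]], "%Y-%m-%d")
    utils::write.csv(x, file.path(dir_path, paste0(tb, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  }
  utils::write.csv(
    data.frame(observation_start = format(db$observation_start, "%Y-%m-%d"),
               observation_end = format(db$observation_end, "%Y-%m-%d")),
    file.path(dir_path, "observation.csv"), row.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(dir_path)
}

#' Load a claims database from delimited files
#'
#' Reads the table layout written by [write_claims()]. A missing table file
#' is fatal and names the table; an unparsable date is fatal and names the
#' table and row.
#'
#' @param dir_path directory holding the five CSV tables (and optionally
#'   `observation.csv`).
#' @param observation_start,observation_end observation window, used when no
#'   `observation.csv` is present.
#' @return a [claims_db()] object.
#' @export
load_claims <- function(dir_path,
                        observation_start = as.Date("2008-01-01"),
                        observation_end = as.Date("2013-12-31")) {
  paths <- file.path(dir_path, paste0(CLAIMS_TABLES, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing))
    stopf("missing claims table(s): %s",
          paste(CLAIMS_TABLES[missing], collapse = ", "))
  obs_path <- file.path(dir_path, "observation.csv")
  if (file.exists(obs_path)) {
    ob <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
    observation_start <- as.Date(ob$observation_start[1])
    observation_end <- as.Date(ob$observation_end[1])
  }
  raw <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE,
                colClasses = "character", fileEncoding = "UTF-8")
  names(raw) <- CLAIMS_TABLES

  parse_date <- function(x, table, col, required = TRUE) {
    x[!nzchar(x)] <- NA_character_
    d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
    bad <- if (required) is.na(d) else (!is.na(x) & is.na(d))
    if (any(bad))
      stopf("table '%s': unparsable %s at row %d ('%s')", table, col,
            which(bad)[1], x[which(bad)[1]])
    d
  }
  ins <- raw$insurants
  if (nrow(ins)) {
    ins$birth_year <- as.integer(ins$birth_year)
    ins$enroll_start <- parse_date(ins$enroll_start, "insurants", "enroll_start")
    ins$enroll_end <- parse_date(ins$enroll_end, "insurants", "enroll_end")
    ins$death_date <- parse_date(ins$death_date, "insurants", "death_date",
                                 required = FALSE)
  }
  dp <- raw$dispensations
  if (nrow(dp)) {
    dp$dispense_date <- parse_date(dp$dispense_date, "dispensations",
                                   "dispense_date")
    dp$cost <- as.numeric(dp$cost)
  }
  ad <- raw$admissions
  if (nrow(ad)) {
    ad$admit_date <- parse_date(ad$admit_date, "admissions", "admit_date")
    ad$discharge_date <- parse_date(ad$discharge_date, "admissions",
                                    "discharge_date")
    ad$drg_cost <- as.numeric(ad$drg_cost)
  }
  op <- raw$outpatient
  if (nrow(op)) {
    op$n_contacts <- as.integer(op$n_contacts)
    op$prescriber_of_aed <- as.logical(op$prescriber_of_aed)
    for (cc in c("cost", "ancillary_cost", "equipment_cost", "dialysis_cost"))
      op[[cc]] <- as.numeric(op[[cc]])
  }
  db <- claims_db(insurants = if (nrow(ins)) ins else NULL,
                  diagnoses = if (nrow(raw$diagnoses)) raw$diagnoses else NULL,
                  dispensations = if (nrow(dp)) dp else NULL,
                  admissions = if (nrow(ad)) ad else NULL,
                  outpatient = if (nrow(op)) op else NULL,
                  observation_start = observation_start,
                  observation_end = observation_end)
  check_window <- function(table, dates, col) {
    bad <- !is.na(dates) & (dates < observation_start | dates > observation_end)
    if (any(bad))
      stopf("table '%s': %s outside observation window at row %d (%s)",
            table, col, which(bad)[1], format(dates[which(bad)[1]]))
  }
  check_window("dispensations", db$dispensations$dispense_date,
               "dispense_date")
  check_window("admissions", db$admissions$admit_date, "admit_date")
  check_window("admissions", db$admissions$discharge_date, "discharge_date")
  db
}

# Split a semicolon-joined code list field into a character vector.
split_codes <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}
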