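# ICD code sets: named collections of prefixes and three-character ranges
# (e.g. "S00-S09") used for comorbidity and injury prevalence comparisons.
# The published analysis names some sets only informally ("depression",
# "vascular disorders"); the defaults below are explicit assumptions and can
# be overridden via a plain-text config file.

#' Define an ICD code set
#'
#' A code set is a named list of ICD-10 prefixes (`"F06"`, `"G40"`) and/or
#' ranges over the first three characters (`"S00-S09"`). Ranges must share
#' the letter and satisfy low <= high. `settings` restricts where matching
#' diagnoses may come from: `"any"` (default) uses every diagnosis record,
#' `"inpatient_primary"` only inpatient primary diagnoses.
#'
#' @param name label for the set.
#' @param codes character vector of prefixes and/or `"Xnn-Xmm"` ranges.
#' @param settings `"any"` or `"inpatient_primary"`.
#' @return object of class `code_set`.
#' @export
#' @examples
#' head_injury <- code_set("head_injury", "S00-S09")
#' icd_in_set(c("S06.1", "S10.0"), head_injury)
code_set <- function(name, codes, settings = "any") {
  codes <- toupper(trimws(codes))
  codes <- gsub("–", "-", codes)  # en-dash in printed ranges
  is_range <- grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", codes)
  is_prefix <- grepl("^[A-Z][0-9]{0,2}(\\.[0-9]+)?$", codes)
  if (any(!is_range & !is_prefix))
    stopf("code set '%s': malformed entry '%s'", name,
          codes[!is_range & !is_prefix][1])
  for (r in codes[is_range]) {
    lo <- substr(r, 1, 3); hi <- substr(r, 5, 7)
    if (substr(lo, 1, 1) != substr(hi, 1, 1) || lo > hi)
      stopf("code set '%s': ill-formed range '%s' (same letter, low<=high)",
            name, r)
  }
  structure(list(name = name, codes = codes, is_range = is_range,
                 settings = match.arg(settings, c("any", "inpatient_primary"))),
            class = "code_set")
}

#' Test ICD codes for membership in a code set
#'
#' Prefix entries match by case-insensitive prefix on the printed code;
#' range entries match on the first three characters (so `"S00-S09"` matches
#' `"S06.1"` but not `"S10.0"`).
#'
#' @param icd_codes character vector of ICD-10 codes.
#' @param set a [code_set()].
#' @return logical vector.
#' @export
icd_in_set <- function(icd_codes, set) {
  stopifnot(inherits(set, "code_set"))
  icd <- toupper(trimws(icd_codes))
  hit <- rep(FALSE, length(icd))
  icd3 <- substr(icd, 1, 3)
  for (i in seq_along(set$codes)) {
    if (set$is_range[i]) {
      lo <- substr(set$codes[i], 1, 3); hi <- substr(set$codes[i], 5, 7)
      hit <- hit | (icd3 >= lo & icd3 <= hi)
    } else {
      hit <- hit | startsWith(icd, set$codes[i])
    }
  }
  hit
}

#' Default comorbidity and injury code sets
#'
#' The conditions compared between SDRE cases and matched controls, with the
#' ICD-10 blocks used here. Sets whose composition the source material states
#' explicitly: organic mental disorders F06, somatoform disorders F45,
#' personality/behavioural disorders F07, head injuries S00-S09, trunk/limb
#' injuries T08-T14, knee/lower leg S80-S89, ankle/foot S90-S99. Sets named
#' only informally are explicit assumptions here: depression F32-F33,
#' vascular disorders I60-I79 plus G45, gastrointestinal disorders K20-K93,
#' hypertension I10-I15.
#'
#' @return named list of [code_set()] objects.
#' @export
default_code_sets <- function() {
  specs <- list(
    depression = c("F32-F33"),
    organic_mental = c("F06"),
    somatoform = c("F45"),
    personality = c("F07"),
    gastrointestinal = c("K20-K93"),
    vascular = c("I60-I79", "G45"),
    hypertension = c("I10-I15"),
    head_injury = c("S00-S09"),
    trunk_limb_injury = c("T08-T14"),
    knee_lower_leg_injury = c("S80-S89"),
    ankle_foot_injury = c("S90-S99")
  )
  out <- lapply(names(specs), function(nm) code_set(nm, specs[[nm]]))
  names(out) <- names(specs)
  out
}

#' Read code sets from a plain-text config file
#'
#' One set per line: `name: CODES | settings`, codes comma-separated, the
#' `| settings` part optional. Lines starting with `#` and blank lines are
#' ignored. See `system.file("extdata", "codesets.cfg", package =
#' "sdreburden")` for the default file.
#'
#' @param path config file path.
#' @return named list of [code_set()] objects.
#' @export
read_code_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stopf("malformed code-set line: '%s'", ln)
    nm <- trimws(parts[1])
    rhs <- trimws(paste(parts[-1], collapse = ":"))
    seg <- strsplit(rhs, "|", fixed = TRUE)[[1]]
    codes <- trimws(strsplit(seg[1], ",", fixed = TRUE)[[1]])
    settings <- if (length(seg) > 1) trimws(seg[2]) else "any"
    out[[nm]] <- code_set(nm, codes, settings)
  }
  out
}
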