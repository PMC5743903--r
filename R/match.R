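# Matched comparison cohort: for each case, up to `ratio` epilepsy-free
# insurants with the same birth year and sex, enrolled at the case's index
# date, sampled uniformly without replacement. Controls inherit the case's
# index date as pseudo-index so cohort time is aligned.

#' Draw an age/sex-matched epilepsy-free comparison cohort
#'
#' Exact matching on birth year (optionally widened to +/- `age_tolerance`
#' years) and sex. Eligible controls have no diagnosis record with the
#' epilepsy ICD prefix in any setting or position at any time, are not
#' themselves cases, and are alive and enrolled at the case's index date
#' (so cohort time can start there). Sampling is
#' uniform without replacement across the whole cohort: a control serves at
#' most one case. When a case's pool is exhausted the achieved ratio is
#' recorded as a shortfall, never silently padded.
#'
#' Determinism: each case samples from its eligible pool with an RNG
#' sub-stream derived from `seed` and the case id, so a fixed seed yields a
#' fixed cohort and, while pools are ample, one case's controls do not
#' depend on which other cases are present. Cases compete for scarce
#' controls in ascending `insurant_id` order.
#'
#' @param db a [claims_db()] object.
#' @param cases an `sdre_cases` data frame from [identify_sdre_cases()]
#'   (columns `insurant_id`, `index_date`).
#' @param ratio target controls per case (default 20).
#' @param seed integer seed for the sampling sub-streams.
#' @param epilepsy_icd_prefix ICD prefix excluding controls (default `"G40"`).
#' @param age_tolerance allowed |birth-year difference| (default 0: exact).
#' @return object of class `matched_cohort`: list with `pairs` (data frame
#'   `case_id`, `control_id`), `pseudo_index` (data frame `control_id`,
#'   `pseudo_index`), `ratio`, and `shortfalls` (data frame `case_id`,
#'   `matched`, `requested`; zero rows when every case reached the ratio).
#' @export
match_controls <- function(db, cases, ratio = 20L, seed = 1L,
                           epilepsy_icd_prefix = "G40", age_tolerance = 0L) {
  stopifnot(inherits(db, "claims_db"))
  ratio <- as.integer(ratio)
  ins <- db$insurants
  epi_ids <- unique(db$diagnoses$insurant_id[
    code_startswith(db$diagnoses$icd_code, epilepsy_icd_prefix)])
  pool <- ins[!(ins$insurant_id %in% epi_ids) &
                !(ins$insurant_id %in% cases$insurant_id), , drop = FALSE]

  case_meta <- merge(cases[, c("insurant_id", "index_date")],
                     ins[, c("insurant_id", "birth_year", "sex")],
                     by = "insurant_id")
  case_meta <- case_meta[order(case_meta$insurant_id), , drop = FALSE]

  taken <- new.env(parent = emptyenv())
  pairs <- vector("list", nrow(case_meta))
  shortfalls <- list()
  pseudo <- vector("list", nrow(case_meta))

  for (i in seq_len(nrow(case_meta))) {
    cs <- case_meta[i, ]
    elig <- pool$insurant_id[
      abs(pool$birth_year - cs$birth_year) <= age_tolerance &
        pool$sex == cs$sex &
        pool$enroll_start <= cs$index_date &
        pool$enroll_end >= cs$index_date &
        (is.na(pool$death_date) | pool$death_date >= cs$index_date)]
    elig <- sort(elig)  # stable pool order, independent of table order
    got <- character(0)
    if (length(elig)) {
      perm <- with_seed(substream_seed(seed, cs$insurant_id),
                        sample.int(length(elig)))
      for (j in perm) {
        cid <- elig[j]
        if (!is.null(taken[[cid]])) next
        got <- c(got, cid)
        taken[[cid]] <- TRUE
        if (length(got) >= ratio) break
      }
    }
    if (length(got) < ratio)
      shortfalls[[length(shortfalls) + 1]] <-
        data.frame(case_id = cs$insurant_id, matched = length(got),
                   requested = ratio, stringsAsFactors = FALSE)
    if (length(got)) {
      pairs[[i]] <- data.frame(case_id = cs$insurant_id, control_id = got,
                               stringsAsFactors = FALSE)
      pseudo[[i]] <- data.frame(control_id = got,
                                pseudo_index = rep(cs$index_date,
                                                   length(got)))
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  if (is.null(pairs))
    pairs <- data.frame(case_id = character(), control_id = character(),
                        stringsAsFactors = FALSE)
  pseudo <- if (length(pseudo)) do.call(rbind, pseudo) else NULL
  if (is.null(pseudo))
    pseudo <- data.frame(control_id = character(),
                         pseudo_index = as.Date(character()))
  rownames(pairs) <- rownames(pseudo) <- NULL
  structure(list(pairs = pairs, pseudo_index = pseudo, ratio = ratio,
                 shortfalls = if (length(shortfalls))
                   do.call(rbind, shortfalls) else
                     data.frame(case_id = character(), matched = integer(),
                                requested = integer(),
                                stringsAsFactors = FALSE)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort>", nrow(x$pairs), "controls for",
      length(unique(x$pairs$case_id)), "cases (target ratio",
      paste0(x$ratio, ":1)"), "\n")
  if (nrow(x$shortfalls))
    cat("  shortfalls for", nrow(x$shortfalls), "case(s); worst",
        min(x$shortfalls$matched), "of", x$ratio, "\n")
  invisible(x)
}

# Control cohort in the same shape as a case cohort: insurant_id + index_date
# (the matched case's index, i.e. the pseudo-index).
control_cohort <- function(matched) {
  data.frame(insurant_id = matched$pseudo_index$control_id,
             index_date = matched$pseudo_index$pseudo_index,
             stringsAsFactors = FALSE)
}
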