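# Independent oracles: deliberately naive re-implementations used to check
# the package's algorithms, written as direct transcriptions of the
# definitions (enumerate every window / every event time), not as copies of
# the production code paths.

# Brute-force rolling-window scan: for every dispensation date d inside the
# identification interval, count the distinct prefix-matching substances
# with at least one dispensation in (d - window, d]; return the earliest d
# reaching k, with the substances in that window.
brute_force_index <- function(dispensations, config = phenotype_config()) {
  keep <- toupper(substr(dispensations$atc_code, 1,
                         nchar(config$aed_atc_prefix))) ==
    toupper(config$aed_atc_prefix)
  d <- dispensations[keep, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  dates <- as.Date(d$dispense_date)
  best <- NULL
  for (i in order(dates)) {
    dd <- dates[i]
    if (dd < config$identification_start || dd > config$identification_end)
      next
    subs <- character(0)
    for (s in unique(toupper(d$atc_code))) {
      ds <- dates[toupper(d$atc_code) == s]
      if (any(ds > dd - config$window_days & ds <= dd))
        subs <- c(subs, s)
    }
    if (length(subs) >= config$k_distinct) {
      best <- list(index_date = dd, qualifying_substances = sort(subs))
      break
    }
  }
  best
}

# Hand-rolled product-limit loop over every distinct event time.
km_brute <- function(durations, events) {
  s <- 1
  out <- NULL
  for (t in sort(unique(durations[as.logical(events)]))) {
    n <- sum(durations >= t)
    d <- sum(durations == t & as.logical(events))
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, n_risk = n, n_event = d,
                                 survival = s))
  }
  out
}

# Random one-person prescription history for fuzzing the window scan.
random_history <- function(n_max = 50,
                           substances = c("N03AX14", "N03AX09", "N03AG01",
                                          "N03AX18", "N03AX11", "N03AF01",
                                          "N03AF02", "N03AX16"),
                           include_other = TRUE) {
  n <- sample.int(n_max, 1)
  pool <- substances
  if (include_other) pool <- c(pool, "N05BA06", "N02BE01")
  data.frame(
    insurant_id = "X",
    dispense_date = as.Date("2008-01-01") +
      sample.int(6 * 365, n, replace = TRUE) - 1,
    atc_code = sample(pool, n, replace = TRUE),
    substance_name = "x", cost = 0,
    stringsAsFactors = FALSE)
}
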