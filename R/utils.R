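# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded components never disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  code
}

# Deterministic 31-bit polynomial hash of strings; basis for per-entity RNG
# sub-streams (stable across sessions, unlike any session hash).
id_hash <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 0
    for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Sub-stream seed derived from a master seed and an entity id. Keeps per-entity
# draws independent of processing order and of other entities.
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + id_hash(id)) %% 2147483647)
}

## ---- calendar quarters ("YYYYQn") -----------------------------------------

quarter_of <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  q <- (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L
  sprintf("%04dQ%d", y, q)
}

quarter_ok <- function(q) grepl("^[0-9]{4}Q[1-4]$", q)

quarter_start <- function(q) {
  if (length(q) == 0) return(as.Date(character()))
  y <- substr(q, 1, 4)
  m <- c("01", "04", "07", "10")[as.integer(substr(q, 6, 6))]
  as.Date(paste(y, m, "01", sep = "-"))
}

quarter_end <- function(q) {
  y <- as.integer(substr(q, 1, 4))
  k <- as.integer(substr(q, 6, 6))
  ny <- ifelse(k == 4L, y + 1L, y)
  nk <- ifelse(k == 4L, 1L, k + 1L)
  as.Date(sprintf("%04d-%02d-01", ny, (nk - 1L) * 3L + 1L)) - 1
}

# Representative day of a quarter, used to place quarter-resolution records
# inside day-resolution analysis periods.
quarter_midpoint <- function(q) quarter_start(q) + 45

## ---- code matching ---------------------------------------------------------

# Case-insensitive prefix match on printed codes (ICD, ATC, OPS).
code_startswith <- function(codes, prefix) {
  startsWith(toupper(trimws(codes)), toupper(trimws(prefix)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
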