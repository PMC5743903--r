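# Self-contained statistical kernel: Pearson chi-square for 2x2 tables and
# the Kaplan-Meier product-limit estimator with Greenwood variance. Written
# out explicitly so every number the reports cite traces to these few lines;
# stats::chisq.test and survival::survfit serve as independent cross-checks
# in the test suite only.

#' Pearson chi-square test for a 2x2 table
#'
#' Statistic \eqn{\sum (O-E)^2/E} with expected counts from the margins,
#' 1 degree of freedom, two-sided p-value from the chi-square survival
#' function. No continuity correction by default; set `correction = TRUE`
#' for the Yates-corrected statistic.
#'
#' @param a,b,c,d cell counts, row-wise (`a`,`b` first row). Alternatively
#'   pass a 2x2 matrix as `a`.
#' @param correction apply the Yates continuity correction.
#' @return list with `statistic`, `df` (always 1), `p_value` and the
#'   `expected` cell counts.
#' @export
#' @examples
#' chi_square_2x2(215, 554, 1538, 13842)$p_value
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           correction = FALSE) {
  # note: arguments c and d shadow base::c/stats-free code below avoids both
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    m <- a
  } else {
    m <- matrix(0, 2, 2)
    m[1, 1] <- a; m[1, 2] <- b; m[2, 1] <- c; m[2, 2] <- d
  }
  if (any(m < 0) || anyNA(m)) stopf("cell counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (n <= 0) stopf("empty table")
  if (any(rs == 0)) stopf("zero row margin (row %d)", which(rs == 0)[1])
  if (any(cs == 0)) stopf("zero column margin (column %d)", which(cs == 0)[1])
  expected <- outer(rs, cs) / n
  dev <- abs(m - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic, df = 1L,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Kaplan-Meier product-limit survival curve
#'
#' Standard product-limit estimate: at each distinct event time t with d
#' events among n at risk, survival multiplies by (1 - d/n). Subjects
#' censored exactly at an event time are counted at risk for that time and
#' removed afterwards (the usual events-before-censoring convention).
#' Greenwood's formula provides the variance.
#'
#' @param durations positive follow-up durations (days from index).
#' @param events logical/0-1 vector; `TRUE` = death observed, `FALSE` =
#'   censored at `duration`.
#' @return object of class `km_curve`: data-frame-like list with `time`
#'   (distinct event times, ascending), `n_risk`, `n_event`, `n_censored`
#'   (censorings at exactly that time), `survival`, `variance`, plus
#'   attributes `n` and `max_time`.
#' @export
#' @examples
#' km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$survival  # 2/3, 1/3, 0
km_curve <- function(durations, events) {
  durations <- as.numeric(durations)
  events <- as.logical(events)
  if (length(durations) != length(events))
    stopf("durations and events differ in length")
  if (anyNA(durations) || anyNA(events)) stopf("missing values not allowed")
  if (any(durations <= 0)) stopf("durations must be positive")
  times <- sort(unique(durations[events]))
  n_risk <- n_event <- n_cens <- integer(length(times))
  surv <- var_acc <- numeric(length(times))
  s <- 1
  acc <- 0  # Greenwood sum d / (n (n - d))
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk[i] <- sum(durations >= t)
    n_event[i] <- sum(durations == t & events)
    n_cens[i] <- sum(durations == t & !events)
    s <- s * (1 - n_event[i] / n_risk[i])
    if (n_risk[i] > n_event[i])
      acc <- acc + n_event[i] / (n_risk[i] * (n_risk[i] - n_event[i]))
    surv[i] <- s
    var_acc[i] <- s^2 * acc
  }
  structure(list(time = times, n_risk = n_risk, n_event = n_event,
                 n_censored = n_cens, survival = surv, variance = var_acc),
            n = length(durations), max_time = max(durations),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", attr(x, "n"), "subjects,", sum(x$n_event), "events at",
      length(x$time), "distinct times\n")
  if (length(x$time))
    cat("  final survival", signif(x$survival[length(x$survival)], 4),
        "at t =", x$time[length(x$time)], "\n")
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_at_risk = x$n_risk, n_events = x$n_event,
             n_censored = x$n_censored, survival = x$survival,
             variance = x$variance)
}

#' @export
plot.km_curve <- function(x, xlab = "days from index", ylab = "survival",
                          ...) {
  t <- c(0, x$time)
  s <- c(1, x$survival)
  graphics::plot(t, s, type = "s", ylim = c(0, 1), xlab = xlab, ylab = ylab,
                 ...)
  invisible(x)
}

#' Cumulative mortality at a horizon
#'
#' Reads 1 - S(horizon) off a [km_curve()], using the step-function value at
#' the largest event time at or before the horizon. A horizon beyond the
#' largest observed duration is an extrapolation and raises a warning.
#'
#' @param curve a [km_curve()].
#' @param horizon_days horizon in days from index.
#' @return proportion dead by the horizon.
#' @export
cumulative_mortality <- function(curve, horizon_days) {
  stopifnot(inherits(curve, "km_curve"))
  if (horizon_days > attr(curve, "max_time"))
    warning("horizon beyond observed follow-up; survival extrapolated ",
            "from the last step", call. = FALSE)
  at <- curve$time <= horizon_days
  s <- if (any(at)) curve$survival[max(which(at))] else 1
  1 - s
}

#' Two-sample log-rank test
#'
#' Provided as an extra beyond the chi-square/Kaplan-Meier core: the
#' original comparison showed survival curves without naming a curve test.
#' Standard Mantel-Cox statistic with hypergeometric variance.
#'
#' @param durations1,events1 follow-up and event indicator, group 1.
#' @param durations2,events2 follow-up and event indicator, group 2.
#' @return list with `statistic` (chi-square, 1 df), `p_value`, and the
#'   observed/expected events per group.
#' @export
logrank_test <- function(durations1, events1, durations2, events2) {
  d <- c(as.numeric(durations1), as.numeric(durations2))
  e <- c(as.logical(events1), as.logical(events2))
  g <- rep(1:2, c(length(durations1), length(durations2)))
  if (any(d <= 0)) stopf("durations must be positive")
  times <- sort(unique(d[e]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n1 <- sum(d >= t & g == 1); n2 <- sum(d >= t & g == 2)
    n <- n1 + n2
    dt <- sum(d == t & e)
    d1 <- sum(d == t & e & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + dt * n1 / n
    if (n > 1) v <- v + dt * (n1 / n) * (n2 / n) * (n - dt) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed1 = o1, expected1 = e1)
}
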