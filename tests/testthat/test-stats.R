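test_that("chi-square statistic matches the closed form and its invariances", {
  # proportional table: no association
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_identical(flat$statistic, 0)
  expect_identical(flat$p_value, 1)

  # closed-form arithmetic oracle, written out from sum((O-E)^2/E)
  a <- 215; b <- 554; cc <- 1538; dd <- 13842
  n <- a + b + cc + dd
  e <- outer(c(a + b, cc + dd), c(a + cc, b + dd)) / n
  o <- matrix(c(a, cc, b, dd), 2)
  want <- sum((o - e)^2 / e)
  got <- chi_square_2x2(a, b, cc, dd)
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_lt(abs(got$statistic - want), 1e-9)
  expect_identical(got$df, 1L)

  # scale: doubling all cells doubles the statistic
  expect_equal(chi_square_2x2(2 * a, 2 * b, 2 * cc, 2 * dd)$statistic,
               2 * got$statistic, tolerance = 1e-12)

  # transpose and row-swap invariance
  expect_equal(chi_square_2x2(a, cc, b, dd)$statistic, got$statistic)
  expect_equal(chi_square_2x2(cc, dd, a, b)$statistic, got$statistic)

  # zero margin is an error naming the margin
  expect_error(chi_square_2x2(0, 0, 5, 5), "row")
  expect_error(chi_square_2x2(0, 5, 0, 5), "column")
})

test_that("chi-square agrees with stats::chisq.test on fuzzed tables", {
  withr::local_seed(31)
  for (i in 1:50) {
    m <- matrix(rpois(4, 40) + 1, 2)
    ours <- chi_square_2x2(m)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    ours_y <- chi_square_2x2(m, correction = TRUE)
    ref_y <- suppressWarnings(chisq.test(m, correct = TRUE))
    expect_equal(ours_y$statistic, unname(ref_y$statistic),
                 tolerance = 1e-12)
  }
})

test_that("product-limit estimate follows the hand-worked examples", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  # all censored: survival identically one, mortality zero
  km0 <- km_curve(c(5, 8, 13), c(FALSE, FALSE, FALSE))
  expect_length(km0$time, 0)
  expect_identical(cumulative_mortality(km0, 10), 0)

  expect_equal(cumulative_mortality(km, 2), 2 / 3)
  expect_equal(cumulative_mortality(km, 2.5), 2 / 3)
  expect_warning(cumulative_mortality(km, 10), "extrapolat")

  expect_error(km_curve(c(-1, 2), c(TRUE, TRUE)), "positive")
})

test_that("without censoring the curve equals the empirical survivor function", {
  withr::local_seed(7)
  for (i in 1:20) {
    d <- sample.int(30, sample.int(25, 1) + 3, replace = TRUE)
    km <- km_curve(d, rep(TRUE, length(d)))
    for (j in seq_along(km$time))
      expect_equal(km$survival[j], mean(d > km$time[j]))
    # cumulative mortality equals the simple event fraction at the horizon
    expect_equal(cumulative_mortality(km, max(d)), 1)
    h <- stats::median(d)
    expect_equal(cumulative_mortality(km, h), mean(d <= h))
  }
})

test_that("fuzzed curves equal the brute-force loop and survival::survfit", {
  skip_if_not_installed("survival")
  withr::local_seed(13)
  for (i in 1:100) {
    n <- sample.int(30, 1) + 2
    d <- sample.int(40, n, replace = TRUE)
    e <- runif(n) < 0.7
    if (!any(e)) e[1] <- TRUE
    km <- km_curve(d, e)
    ref <- km_brute(d, e)
    expect_equal(km$time, ref$time)
    expect_equal(km$survival, ref$survival, tolerance = 1e-12)
    sf <- survival::survfit(survival::Surv(d, e) ~ 1)
    at <- summary(sf, times = km$time)
    expect_equal(km$survival, at$surv, tolerance = 1e-9)
    # survfit leaves the Greenwood SE undefined once survival reaches zero
    pos <- km$survival > 0
    expect_equal(sqrt(km$variance)[pos], at$std.err[pos], tolerance = 1e-9)
  }
})

test_that("log-rank test is null on identical groups and tracks survdiff", {
  skip_if_not_installed("survival")
  d <- c(3, 5, 7, 11, 13); e <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(logrank_test(d, e, d, e)$statistic, 0)
  withr::local_seed(17)
  d1 <- rexp(40, 1 / 10); d2 <- rexp(40, 1 / 6)
  e1 <- runif(40) < 0.8; e2 <- runif(40) < 0.8
  ours <- logrank_test(d1, e1, d2, e2)
  ref <- survival::survdiff(survival::Surv(c(d1, d2), c(e1, e2)) ~
                              rep(1:2, each = 40))
  expect_equal(ours$statistic, ref$chisq, tolerance = 1e-9)
})
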