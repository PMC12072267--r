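test_that("incidence rates per 10,000 match published national values", {
  expect_equal(round_half_away(incidence_rate(11512, 11371000), 2), 10.12)
  expect_equal(round_half_away(incidence_rate(16732, 22209000), 2), 7.53)
  expect_equal(incidence_rate(0, 1e6), 0)
  expect_error(incidence_rate(5, 0), "population")
  expect_error(incidence_rate(-1, 10), "count")
})

test_that("expected counts from baseline rates reproduce published arithmetic", {
  expect_equal(expected_count(6.5, 11371000), 7391)
  expect_equal(expected_count(3.87, 11838000), 4581)
  expect_equal(expected_count(0, 123), 0)
  expect_error(expected_count(-1, 10), "rate_by")
})

test_that("excess counts are signed differences and sum over strata", {
  expect_equal(excess_count(16732, 11972), 4760)
  expect_equal(excess_count(11512, 7391), 4121)
  expect_equal(excess_count(100, 100), 0)
  expect_equal(excess_count(50, 80), -30)
  # sum over strata equals total excess, and swapping O/E flips the sign
  set.seed(3)
  for (i in 1:20) {
    o <- rpois(3, 500); e <- rpois(3, 500)
    expect_equal(sum(excess_count(o, e)), excess_count(sum(o), sum(e)))
    expect_equal(excess_count(o, e), -excess_count(e, o))
  }
})

test_that("round-trip: rate -> expected count recovers the baseline count", {
  set.seed(7)
  for (i in 1:50) {
    pop <- runif(1, 1e5, 2e7)
    count <- rpois(1, runif(1, 10, 2e4))
    back <- expected_count(incidence_rate(count, pop), pop)
    expect_lte(abs(back - count), 1)
  }
})

test_that("normal Poisson interval is mean +/- z sqrt(mean), clipped at zero", {
  b <- poisson_interval(7391, 0.95, "normal")
  expect_equal(c(b$low, b$high), c(7222.5, 7559.5), tolerance = 1e-4)
  z <- qnorm(0.975)
  expect_equal(b$low, 7391 - z * sqrt(7391))
  b0 <- poisson_interval(0, 0.95, "normal")
  expect_equal(c(b0$low, b0$high), c(0, 0))
  expect_equal(poisson_interval(2, 0.95, "normal")$low, 0)  # clipped
  expect_error(poisson_interval(10, 1.5), "level")
  expect_error(poisson_interval(-1), "mean")
})

test_that("exact Poisson interval matches a pmf-summation oracle", {
  # oracle: solve the tail equations P(X >= m; lo) = a/2 and
  # P(X <= m; hi) = a/2 by root-finding on explicit pmf sums
  pmf_sum <- function(lambda, from, to)
    sum(exp(-lambda + (from:to) * log(lambda) - lgamma(from:to + 1)))
  for (m in c(3, 10, 25)) {
    b <- poisson_interval(m, 0.95, "exact")
    lo <- uniroot(function(l) (1 - pmf_sum(l, 0, m - 1)) - 0.025,
                  c(1e-6, 4 * m + 20), tol = 1e-10)$root
    hi <- uniroot(function(l) pmf_sum(l, 0, m) - 0.025,
                  c(1e-6, 4 * m + 20), tol = 1e-10)$root
    expect_equal(b$low, lo, tolerance = 1e-6)
    expect_equal(b$high, hi, tolerance = 1e-6)
  }
})

test_that("interval width grows as sqrt(mean); exact ~ normal at large mean", {
  w <- function(m, meth) {
    b <- poisson_interval(m, 0.95, meth); b$high - b$low
  }
  means <- c(1000, 4000, 16000)
  for (meth in c("normal", "exact")) {
    widths <- vapply(means, w, numeric(1), meth = meth)
    expect_equal(widths[2] / widths[1], 2, tolerance = 0.05)
    expect_equal(widths[3] / widths[2], 2, tolerance = 0.05)
  }
  for (m in means) {
    expect_equal(w(m, "exact") / w(m, "normal"), 1, tolerance = 0.02)
  }
})

test_that("chi-square goodness of fit follows the Pearson formula", {
  g <- goodness_of_fit(c(11512, 5220), c(7391, 4581))
  expect_equal(g$chi2, 4121^2 / 7391 + 639^2 / 4581)
  expect_equal(g$chi2, 2386.9, tolerance = 1e-4)
  expect_equal(g$df, 1)
  expect_lt(g$p, 1e-10)

  same <- goodness_of_fit(c(10, 20), c(10, 20))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  expect_equal(goodness_of_fit(c(5, 5), c(4, 6))$chi2, 1 / 4 + 1 / 6)

  expect_error(goodness_of_fit(5, 5), "cells")
  expect_error(goodness_of_fit(c(5, 5), c(0, 10)), "expected")
})

test_that("scenario-level expectation assembles strata, totals and GOF", {
  scn <- romania_scenario()
  e <- baseline_expectation(scn)
  expect_equal(e$strata$expected_ey, c(7391, 4581))
  expect_equal(e$totals$expected_ey, 11972)
  expect_equal(e$strata$excess, c(4121, 639))
  expect_equal(e$totals$excess, 4760)
  # printed baseline rates take precedence over recomputed quotients
  expect_equal(e$strata$rate_by, c(6.5, 3.87))
  expect_equal(e$gof$df, 1)
  # exact interval brackets the expected count
  expect_true(all(e$strata$ne_low < e$strata$expected_ey &
                  e$strata$expected_ey < e$strata$ne_high))

  single <- scenario(2008, 2018, list(stratum_record("all", 1e6, 1e6, 50, 80)))
  expect_null(baseline_expectation(single)$gof)
})
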