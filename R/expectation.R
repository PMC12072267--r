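# Baseline expectation: what would the end year have looked like had the
# baseline-year fracture rates persisted? The gap between that counterfactual
# and the observed end-year counts is the excess the decomposition explains.

#' Incidence rate per 10,000 inhabitants
#'
#' @param count events observed (>= 0).
#' @param population persons at risk (> 0).
#' @return unrounded rate per 10,000; display rounding is a separate concern
#'   (see [round_half_away()]).
#' @export
#' @examples
#' incidence_rate(11512, 11371000)  # 10.1240...
incidence_rate <- function(count, population) {
  if (any(!is_number(population)) || any(population <= 0))
    fail("incidence_rate: 'population' must be > 0")
  if (any(!is_number(count)) || any(count < 0))
    fail("incidence_rate: 'count' must be >= 0")
  count / population * 1e4
}

#' Expected end-year count from a baseline rate
#'
#' Applies a baseline-year rate to the end-year population and rounds
#' half-away-from-zero to a whole number of fractures. Rounding is applied
#' per stratum; stratum totals are then summed, which is the arithmetic
#' national reports use.
#'
#' @param rate_by baseline rate per 10,000 (>= 0).
#' @param pop_ey end-year population (> 0).
#' @return expected fracture count (integer-valued numeric).
#' @export
#' @examples
#' expected_count(6.5, 11371000)   # 7391
#' expected_count(3.87, 11838000)  # 4581
expected_count <- function(rate_by, pop_ey) {
  if (any(!is_number(rate_by)) || any(rate_by < 0))
    fail("expected_count: 'rate_by' must be >= 0")
  if (any(!is_number(pop_ey)) || any(pop_ey <= 0))
    fail("expected_count: 'pop_ey' must be > 0")
  round_half_away(rate_to_count(rate_by, pop_ey))
}

#' Excess count: observed minus expected
#'
#' The signed number of fractures requiring explanation; negative when fewer
#' events occurred than the baseline rates predict.
#'
#' @param observed_ey,expected_ey end-year observed and expected counts (>= 0).
#' @return signed count.
#' @export
excess_count <- function(observed_ey, expected_ey) {
  if (any(!is_number(observed_ey)) || any(observed_ey < 0) ||
      any(!is_number(expected_ey)) || any(expected_ey < 0))
    fail("excess_count: counts must be >= 0")
  observed_ey - expected_ey
}

#' Confidence interval for an expected count under Poisson assumptions
#'
#' Fracture events are rare relative to the population, so counts are treated
#' as Poisson. `method = "normal"` returns `mean +/- z * sqrt(mean)` clipped
#' at 0. `method = "exact"` inverts the Poisson tail probabilities via the
#' gamma-quantile identity: lower bound `qgamma(a/2, mean)`, upper bound
#' `qgamma(1 - a/2, mean + 1)` (for non-integer `mean` this is the continuous
#' gamma generalisation).
#'
#' @param mean expected count (>= 0).
#' @param level coverage in (0, 1); default 0.95.
#' @param method `"exact"` (default) or `"normal"`.
#' @return an [uncertainty_bounds()] with source `"ci95"` when `level == 0.95`,
#'   else `"custom"`.
#' @export
#' @examples
#' poisson_interval(7391, method = "normal")  # 7391 +/- 1.96 * sqrt(7391)
poisson_interval <- function(mean, level = 0.95,
                             method = c("exact", "normal")) {
  method <- match.arg(method)
  if (!is_number(mean) || length(mean) != 1 || mean < 0)
    fail("poisson_interval: 'mean' must be >= 0")
  if (!is_number(level) || length(level) != 1 || level <= 0 || level >= 1)
    fail("poisson_interval: 'level' must lie in (0, 1)")
  a <- 1 - level
  if (mean == 0) {
    lo <- hi <- 0
    if (method == "exact") hi <- stats::qgamma(1 - a / 2, 1)
  } else if (method == "normal") {
    z <- stats::qnorm(1 - a / 2)
    lo <- max(0, mean - z * sqrt(mean))
    hi <- mean + z * sqrt(mean)
  } else {
    lo <- stats::qgamma(a / 2, mean)
    hi <- stats::qgamma(1 - a / 2, mean + 1)
  }
  uncertainty_bounds(lo, hi, if (isTRUE(all.equal(level, 0.95))) "ci95" else "custom")
}

#' Chi-square goodness of fit of observed to expected counts
#'
#' @param observed,expected numeric vectors of equal length >= 2; every
#'   expected cell must be > 0.
#' @return list with `chi2` (Pearson statistic, sum of (O-E)^2/E), `df`
#'   (cells - 1) and `p` (upper-tail chi-square probability).
#' @export
goodness_of_fit <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 2)
    fail("goodness_of_fit: need >= 2 cells with matching lengths")
  if (any(!is_number(expected)) || any(expected <= 0))
    fail("goodness_of_fit: every 'expected' cell must be > 0")
  if (any(!is_number(observed)) || any(observed < 0))
    fail("goodness_of_fit: 'observed' must be >= 0")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Baseline expectation for a whole scenario
#'
#' Per stratum: effective baseline rate (a supplied `rate_by` override wins
#' over the recomputed `observed_by / pop_by`), end-year rate, expected
#' end-year count, Poisson interval for it, and the excess. Totals sum the
#' per-stratum values; total rates use pooled counts and populations. When
#' the scenario has at least two strata a chi-square goodness-of-fit test of
#' observed vs expected end-year counts is attached.
#'
#' @param scn a `hip_scenario`.
#' @param interval `"exact"` or `"normal"`; default from the scenario options.
#' @param level interval coverage; default from the scenario options.
#' @return object of class `hip_expectation`: `$strata` data frame,
#'   `$totals` list, `$gof` list or `NULL`.
#' @export
baseline_expectation <- function(scn, interval = NULL, level = NULL) {
  stopifnot(inherits(scn, "hip_scenario"))
  interval <- interval %||% scn$options$interval
  level <- level %||% scn$options$level

  rows <- lapply(scn$strata, function(s) {
    r_by <- s$rate_by %||% incidence_rate(s$observed_by, s$pop_by)
    ne <- expected_count(r_by, s$pop_ey)
    ci <- poisson_interval(ne, level = level, method = interval)
    data.frame(sex = s$sex, pop_by = s$pop_by, observed_by = s$observed_by,
               rate_by = r_by, pop_ey = s$pop_ey, observed_ey = s$observed_ey,
               rate_ey = incidence_rate(s$observed_ey, s$pop_ey),
               expected_ey = ne, ne_low = ci$low, ne_high = ci$high,
               excess = excess_count(s$observed_ey, ne),
               rate_by_printed = !is.null(s$rate_by))
  })
  strata <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  tot_ne <- sum(strata$expected_ey)
  tot_ci <- poisson_interval(tot_ne, level = level, method = interval)
  totals <- list(
    pop_by = sum(strata$pop_by), observed_by = sum(strata$observed_by),
    rate_by = incidence_rate(sum(strata$observed_by), sum(strata$pop_by)),
    pop_ey = sum(strata$pop_ey), observed_ey = sum(strata$observed_ey),
    rate_ey = incidence_rate(sum(strata$observed_ey), sum(strata$pop_ey)),
    expected_ey = tot_ne, ne_low = tot_ci$low, ne_high = tot_ci$high,
    excess = sum(strata$excess))

  gof <- if (nrow(strata) >= 2)
    goodness_of_fit(strata$observed_ey, strata$expected_ey) else NULL

  structure(list(strata = strata, totals = totals, gof = gof,
                 interval = interval, level = level),
            class = "hip_expectation")
}

#' @export
print.hip_expectation <- function(x, ...) {
  cat(sprintf("<hip_expectation> expected %s, observed %s, excess %s\n",
              format(x$totals$expected_ey, big.mark = ","),
              format(x$totals$observed_ey, big.mark = ","),
              format(x$totals$excess, big.mark = ",")))
  if (!is.null(x$gof))
    cat(sprintf("  goodness of fit: chi2(%d) = %.1f, p = %.3g\n",
                x$gof$df, x$gof$chi2, x$gof$p))
  invisible(x)
}
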