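# Attribution engine: PARF changes per exposure, the medication term, the
# cumulative-vs-additive overlap adjustment, and aggregation into the modeled
# excess and the percent of the excess explained.
#
# Sign convention (used everywhere in this package): positive contributions
# GENERATE fractures, negative contributions PREVENT them. A harmful exposure
# (RR > 1) whose prevalence rises therefore contributes positively; the
# medication term is always <= 0. Published tables using the same
# "+generated / -prevented" legend line up directly.

#' Population attributable risk fraction (PARF)
#'
#' `PARF = P (RR - 1) / (P (RR - 1) + 1)` for exposure prevalence `P` and
#' relative risk `RR`. Positive for a harmful exposure (RR > 1): the fraction
#' of events attributable to the exposure. Negative for a protective exposure
#' (RR < 1): the fraction by which events would increase were the exposure
#' removed.
#'
#' @param prevalence proportion exposed, in \[0, 1\].
#' @param rr relative risk, > 0.
#' @return PARF in (-Inf, 1). Errors if the denominator `P(RR-1) + 1` is
#'   non-positive (only reachable for strongly protective exposures at high
#'   prevalence, where the inputs are inconsistent).
#' @export
#' @examples
#' parf(0.168, 1.3)   #  0.04798
#' parf(0.552, 0.66)  # -0.23104
parf <- function(prevalence, rr) {
  if (any(!is_number(prevalence)) || any(prevalence < 0 | prevalence > 1))
    fail("parf: 'prevalence' must lie in [0, 1]")
  if (any(!is_number(rr)) || any(rr <= 0))
    fail("parf: 'rr' must be > 0")
  q <- prevalence * (rr - 1)
  den <- q + 1
  if (any(den <= 0))
    fail("parf: invalid input, P(RR-1) + 1 <= 0 (P = %g, RR = %g)",
         prevalence[den <= 0][1], rr[den <= 0][1])
  q / den
}

#' Contribution of one exposure's prevalence change to the excess
#'
#' The expected end-year count scaled by the change in PARF between baseline
#' and end year: `NE_EY * (PARF_EY - PARF_BY)`. Under the package sign
#' convention the result is positive when the change generated fractures
#' (e.g. rising prevalence of a harmful exposure) and negative when it
#' prevented them.
#'
#' @param ne_ey expected end-year count (>= 0).
#' @param p_by,p_ey prevalence at baseline/end year, in \[0, 1\].
#' @param rr relative risk, > 0.
#' @return signed fracture count.
#' @export
#' @examples
#' factor_contribution(7391, 0.168, 0.217, 1.3)  # +97.1 (generated)
#' factor_contribution(7391, 0.051, 0.069, 0.5)  # -70.7 (prevented)
factor_contribution <- function(ne_ey, p_by, p_ey, rr) {
  if (any(!is_number(ne_ey)) || any(ne_ey < 0))
    fail("factor_contribution: 'ne_ey' must be >= 0")
  ne_ey * (parf(p_ey, rr) - parf(p_by, rr))
}

#' Hip-fracture rate in osteoporosis patients
#'
#' The population rate multiplied by the relative risk of hip fracture in
#' osteoporosis patients versus the whole population.
#'
#' @param pop_rate population fracture rate per 10,000 (>= 0).
#' @param osteo_rr relative risk in osteoporosis patients (>= 0).
#' @return rate per 10,000.
#' @export
#' @examples
#' osteoporosis_rate(10.12, 6.4)  # 64.77 (2 dp)
osteoporosis_rate <- function(pop_rate, osteo_rr) {
  if (any(!is_number(pop_rate)) || any(pop_rate < 0) ||
      any(!is_number(osteo_rr)) || any(osteo_rr < 0))
    fail("osteoporosis_rate: inputs must be >= 0")
  pop_rate * osteo_rr
}

#' Fractures prevented by osteoporosis medication
#'
#' `OM x RRR x r_OP / 10,000`: treated users times the treatment's relative
#' risk reduction times the fracture rate they would face untreated. Returned
#' with a negative sign — medication only ever prevents fractures under this
#' model.
#'
#' @param users treated persons (>= 0).
#' @param rrr relative risk reduction, in \[0, 1\].
#' @param r_op fracture rate in osteoporosis patients per 10,000 (>= 0).
#' @return signed count, `<= 0`.
#' @export
#' @examples
#' medication_contribution(100000, 0.53, 64.77)  # -343.3
medication_contribution <- function(users, rrr, r_op) {
  if (any(!is_number(users)) || any(users < 0))
    fail("medication_contribution: 'users' must be >= 0")
  if (any(!is_number(rrr)) || any(rrr < 0 | rrr > 1))
    fail("medication_contribution: 'rrr' must lie in [0, 1]")
  if (any(!is_number(r_op)) || any(r_op < 0))
    fail("medication_contribution: 'r_op' must be >= 0")
  -(users * rrr * r_op / 1e4)
}

#' Overlap adjustment factor (cumulative vs additive risk)
#'
#' Individual attributable fractions are estimated factor by factor, but the
#' exposures overlap in the population; summing them double-counts. The
#' adjustment factor is the ratio of the cumulative risk reduction
#' `CR = 1 - prod(1 - R_i)` to the additive risk reduction `AR = sum(R_i)`,
#' always in (0, 1], equal to 1 when at most one `R_i` is nonzero.
#'
#' @param risk_magnitudes numeric vector of per-factor risk magnitudes `R_i`,
#'   each in \[0, 1); non-empty.
#' @param interpretation free-text tag recording which model quantity was used
#'   as `R_i` (kept in the result for the run log).
#' @return list with `af`, `cr`, `ar`, `interpretation`. When every `R_i` is
#'   zero, `AF` is defined as 1 by continuity (with a message-worthy note in
#'   the `note` field).
#' @export
#' @examples
#' adjustment_factor(c(0.1, 0.2))$af        # 0.9333
#' adjustment_factor(c(0.5, 0.5, 0.5))$af   # 0.5833
adjustment_factor <- function(risk_magnitudes, interpretation = "delta_parf") {
  if (length(risk_magnitudes) == 0)
    fail("adjustment_factor: 'risk_magnitudes' must be non-empty")
  if (any(!is_number(risk_magnitudes)) ||
      any(risk_magnitudes < 0 | risk_magnitudes >= 1))
    fail("adjustment_factor: every R_i must lie in [0, 1)")
  cr <- 1 - prod(1 - risk_magnitudes)
  ar <- sum(risk_magnitudes)
  note <- NULL
  if (ar == 0) {
    af <- 1
    note <- "all risk magnitudes zero; AF defined as 1 by continuity"
  } else {
    af <- cr / ar
  }
  list(af = af, cr = cr, ar = ar, interpretation = interpretation, note = note)
}

#' Adjusted risk-factor component
#'
#' @param contributions signed per-factor counts.
#' @param af adjustment factor in (0, 1].
#' @return `af * sum(contributions)`; 0 for an empty vector.
#' @export
risk_component <- function(contributions, af) {
  if (!is_number(af) || length(af) != 1 || af <= 0 || af > 1)
    fail("risk_component: 'af' must lie in (0, 1]")
  if (length(contributions) == 0) return(0)
  af * sum(contributions)
}

#' Aggregate components into the modeled excess
#'
#' @param nx_med,nx_risk_factors,nx_drugs signed component counts.
#' @param excess total excess to explain; must be nonzero.
#' @return list with `nx_modeled` (the sum) and `percent_explained`
#'   (100 x modeled / excess).
#' @export
#' @examples
#' aggregate_components(-733, 4376, 644, 4760)  # 4287, 90.06%
aggregate_components <- function(nx_med, nx_risk_factors, nx_drugs, excess) {
  if (!is_number(excess) || excess == 0)
    fail("aggregate_components: 'excess' must be nonzero")
  nx_modeled <- nx_med + nx_risk_factors + nx_drugs
  list(nx_modeled = nx_modeled,
       percent_explained = 100 * nx_modeled / excess)
}

#' Share of the total excess
#'
#' @param nx signed contribution.
#' @param excess total excess; nonzero.
#' @return signed percent, `100 * nx / excess`.
#' @export
share_of_total <- function(nx, excess) {
  if (any(!is_number(excess)) || any(excess == 0))
    fail("share_of_total: 'excess' must be nonzero")
  100 * nx / excess
}

# ---- full decomposition -----------------------------------------------------

# internal: per-factor, per-sex PARF table for a scenario
parf_table <- function(scn, ne_by_sex) {
  sexes <- names(scn$strata)
  rows <- list()
  for (f in scn$factors) {
    for (s in sexes) {
      pb <- f$prevalence_by[[s]]
      pe <- f$prevalence_ey[[s]]
      rr <- f$relative_risk[[s]]
      rows[[length(rows) + 1]] <- data.frame(
        factor = f$name, category = f$category, sex = s,
        p_by = pb, p_ey = pe, rr = rr,
        parf_by = parf(pb, rr), parf_ey = parf(pe, rr),
        nx = factor_contribution(ne_by_sex[[s]], pb, pe, rr))
    }
  }
  if (length(rows) == 0)
    return(data.frame(factor = character(), category = character(),
                      sex = character(), p_by = numeric(), p_ey = numeric(),
                      rr = numeric(), parf_by = numeric(), parf_ey = numeric(),
                      nx = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# internal: per-factor risk magnitudes R_i for the overlap adjustment,
# pooled (unweighted mean) across sexes
risk_magnitudes <- function(ct, interpretation) {
  if (nrow(ct) == 0) return(numeric(0))
  per_row <- switch(interpretation,
    delta_parf = abs(ct$parf_ey - ct$parf_by),
    parf_ey = abs(ct$parf_ey),
    none = rep(0, nrow(ct)),
    fail("unknown adjustment interpretation '%s'", interpretation))
  r <- tapply(per_row, ct$factor, mean)
  pmin(as.numeric(r), 1 - 1e-12)
}

#' Decompose the excess fracture count of a scenario
#'
#' Runs the full model: baseline expectation, per-factor per-sex PARF-change
#' contributions, the medication term, the overlap adjustment, and
#' aggregation.
#'
#' Two aggregation tracks are supported. The `"equations"` track recomputes
#' every contribution from the scenario's prevalences, relative risks and
#' user counts. The `"published"` track instead aggregates the
#' reported-outcome annotations (`reported_nx`) carried by the scenario —
#' useful when a source publishes per-row contributions whose upstream
#' stratified inputs are not available, so that totals can be reproduced
#' exactly while the equation-based recomputation is reported alongside.
#'
#' On the equations track the adjustment factor multiplies every factor
#' contribution (risk factors, preventive measures and drug classes alike)
#' but never the medication term. On the published track reported rows
#' already sum to their published totals, so the AF is computed and reported
#' but not applied.
#'
#' @param scn a `hip_scenario`.
#' @param track `"equations"` or `"published"`; default from scenario options
#'   (`"both"` resolves to `"equations"` here — use [run_pipeline()] for both).
#' @param adjustment `"delta_parf"` (default: `R_i = |PARF_EY - PARF_BY|`,
#'   pooled across sexes), `"parf_ey"` (`R_i = |PARF_EY|`) or `"none"`.
#' @param interval,level forwarded to [baseline_expectation()].
#' @return object of class `hip_decomposition` with the expectation, the
#'   per-factor contribution table (`$contributions`, including `nx_adjusted`
#'   and `share`), the medication table (`$medication`), the adjustment
#'   (`$adjustment`), component subtotals `$nx_med`, `$nx_risk`, `$nx_drugs`,
#'   and `$nx_modeled` / `$percent_explained`.
#' @export
decompose_scenario <- function(scn, track = NULL, adjustment = NULL,
                               interval = NULL, level = NULL) {
  stopifnot(inherits(scn, "hip_scenario"))
  track <- track %||% scn$options$track
  if (track == "both") track <- "equations"
  if (!track %in% c("equations", "published"))
    fail("decompose_scenario: 'track' must be 'equations' or 'published'")
  adjustment <- adjustment %||% scn$options$adjustment
  notes <- character(0)

  expectation <- baseline_expectation(scn, interval = interval, level = level)
  exp_df <- expectation$strata
  ne_by_sex <- stats::setNames(exp_df$expected_ey, exp_df$sex)
  rate_by_sex <- stats::setNames(exp_df$rate_by, exp_df$sex)
  excess_total <- expectation$totals$excess

  # PARF table is always computed (the AF needs it on either track)
  ct <- parf_table(scn, ne_by_sex)

  # overlap adjustment over ALL factor specs (risk, preventive, drug classes)
  adj <- if (nrow(ct) > 0 && adjustment != "none") {
    adjustment_factor(risk_magnitudes(ct, adjustment), adjustment)
  } else {
    list(af = 1, cr = NA_real_, ar = NA_real_, interpretation = adjustment,
         note = if (nrow(ct) == 0) "no factors; AF = 1" else "adjustment disabled")
  }
  if (!is.null(adj$note)) notes <- c(notes, adj$note)

  # medication component, per sex: OM_EY x RRR x r_OP(BY) / 10,000
  med_rows <- list()
  for (m in scn$medications) {
    for (s in names(scn$strata)) {
      r_op <- osteoporosis_rate(rate_by_sex[[s]], m$osteo_rr[[s]])
      med_rows[[length(med_rows) + 1]] <- data.frame(
        medication = m$name, sex = s,
        users_by = m$users_by[[s]], users_ey = m$users_ey[[s]],
        rrr = m$rrr, osteo_rr = m$osteo_rr[[s]], r_op = r_op,
        nx = medication_contribution(m$users_ey[[s]], m$rrr, r_op))
    }
  }
  med <- if (length(med_rows) > 0)
    do.call(rbind, c(med_rows, list(make.row.names = FALSE)))
  else data.frame(medication = character(), sex = character(),
                  users_by = numeric(), users_ey = numeric(), rrr = numeric(),
                  osteo_rr = numeric(), r_op = numeric(), nx = numeric())

  if (track == "published") {
    # swap in the reported per-row outcomes
    get_rep <- function(spec, s) {
      if (is.null(spec$reported_nx))
        fail("published track: '%s' carries no reported_nx annotation", spec$name)
      spec$reported_nx[[s]]
    }
    if (nrow(ct) > 0)
      ct$nx <- mapply(function(fn, s) get_rep(scn$factors[[fn]], s),
                      ct$factor, ct$sex)
    if (nrow(med) > 0)
      med$nx <- mapply(function(mn, s) get_rep(scn$medications[[mn]], s),
                       med$medication, med$sex)
    ct$nx_adjusted <- ct$nx  # reported rows already sum to published totals
    notes <- c(notes, sprintf(
      "published track: reported row values aggregated; AF = %.4f reported but not applied",
      adj$af))
  } else {
    ct$nx_adjusted <- if (nrow(ct) > 0) adj$af * ct$nx else numeric(0)
  }

  is_drug <- ct$category == "drug_side_effect"
  nx_risk <- sum(ct$nx_adjusted[!is_drug])
  nx_drugs <- sum(ct$nx_adjusted[is_drug])
  nx_med <- sum(med$nx)

  if (excess_total == 0)
    fail("decompose_scenario: total excess is zero; percent explained undefined")
  agg <- aggregate_components(nx_med, nx_risk, nx_drugs, excess_total)
  ct$share <- if (nrow(ct) > 0) share_of_total(ct$nx_adjusted, excess_total)
              else numeric(0)
  med$share <- if (nrow(med) > 0) share_of_total(med$nx, excess_total)
               else numeric(0)

  structure(list(track = track, expectation = expectation,
                 contributions = ct, medication = med, adjustment = adj,
                 nx_med = nx_med, nx_risk = nx_risk, nx_drugs = nx_drugs,
                 nx_modeled = agg$nx_modeled,
                 percent_explained = agg$percent_explained,
                 excess = excess_total, notes = notes),
            class = "hip_decomposition")
}

#' @export
print.hip_decomposition <- function(x, ...) {
  cat(sprintf("<hip_decomposition> track = %s\n", x$track))
  cat(sprintf("  excess to explain: %s\n", format(x$excess, big.mark = ",")))
  cat(sprintf("  medication %8.1f | risk factors %8.1f | drugs %8.1f\n",
              x$nx_med, x$nx_risk, x$nx_drugs))
  cat(sprintf("  modeled %0.1f = %0.1f%% of the excess (AF = %.4f, %s)\n",
              x$nx_modeled, x$percent_explained, x$adjustment$af,
              x$adjustment$interpretation))
  invisible(x)
}
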