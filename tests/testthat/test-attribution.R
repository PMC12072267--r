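test_that("PARF evaluates the prevalence/relative-risk formula", {
  expect_equal(parf(0.168, 1.3), 0.04798, tolerance = 1e-4)
  expect_equal(parf(0.552, 0.66), -0.23104, tolerance = 1e-4)
  expect_equal(parf(0, 17), 0)
  expect_equal(parf(0.42, 1), 0)
  expect_error(parf(1.2, 1.5), "prevalence")
  expect_error(parf(0.5, 0), "rr")
  # the denominator 1 - P + P*RR stays positive on the whole valid domain,
  # so PARF < 1 even at extreme protective inputs
  expect_lt(parf(1, 1e-6), 1)
})

test_that("property: PARF is monotone in prevalence and sign-symmetric in RR", {
  set.seed(21)
  for (i in 1:50) {
    rr <- exp(runif(1, log(1.01), log(3)))
    p <- sort(runif(2, 0.01, 0.99))
    expect_lt(parf(p[1], rr), parf(p[2], rr))          # increasing, RR > 1
    expect_gt(parf(p[1], 1 / rr), parf(p[2], 1 / rr))  # decreasing, RR < 1
    expect_lt(parf(p[1], rr) * parf(p[1], 1 / rr), 0)  # opposite signs
    expect_lt(parf(p[2], rr), 1)
  }
})

test_that("factor contributions follow NE x (PARF_EY - PARF_BY)", {
  expect_equal(factor_contribution(7391, 0.168, 0.217, 1.3), 97.1,
               tolerance = 1e-3)
  expect_equal(factor_contribution(7391, 0.051, 0.069, 0.5), -70.7,
               tolerance = 1e-3)
  expect_equal(factor_contribution(5000, 0.3, 0.3, 1.9), 0)
  # rising prevalence of a harmful exposure generates fractures (positive)
  expect_gt(factor_contribution(1000, 0.1, 0.3, 1.5), 0)
  # rising prevalence of a protective exposure prevents them (negative)
  expect_lt(factor_contribution(1000, 0.1, 0.3, 0.6), 0)

  set.seed(5)
  for (i in 1:30) {
    ne <- runif(1, 100, 1e4); p <- runif(2, 0.05, 0.9)
    rr <- exp(runif(1, log(0.5), log(2)))
    # linear in NE
    expect_equal(factor_contribution(2 * ne, p[1], p[2], rr),
                 2 * factor_contribution(ne, p[1], p[2], rr))
    # reversing BY/EY flips the sign exactly
    expect_equal(factor_contribution(ne, p[2], p[1], rr),
                 -factor_contribution(ne, p[1], p[2], rr))
  }
})

test_that("osteoporosis rate chain multiplies population rate by RR", {
  expect_equal(osteoporosis_rate(10.12, 6.4), 64.768)
  expect_equal(round_half_away(osteoporosis_rate(10.12, 6.4), 2), 64.77)
  expect_equal(osteoporosis_rate(6.5, 6.4), 41.6)
  expect_equal(osteoporosis_rate(7.7, 1), 7.7)
})

test_that("medication term is users x RRR x rate, always preventive", {
  expect_equal(medication_contribution(100000, 0.53, 64.77), -343.281)
  expect_equal(medication_contribution(12345, 0, 64.77), 0)
  expect_equal(medication_contribution(0, 0.53, 64.77), 0)
  expect_lte(medication_contribution(5e4, 0.4, 30), 0)
  expect_error(medication_contribution(100, 1.2, 30), "rrr")
})

test_that("adjustment factor is cumulative over additive risk", {
  expect_equal(adjustment_factor(0.3)$af, 1)
  expect_equal(adjustment_factor(c(0.1, 0.2))$af, 0.28 / 0.30)
  expect_equal(adjustment_factor(c(0.5, 0.5, 0.5))$af, 0.875 / 1.5)
  z <- adjustment_factor(c(0, 0, 0))
  expect_equal(z$af, 1)
  expect_match(z$note, "continuity")
  expect_error(adjustment_factor(numeric(0)), "non-empty")
  expect_error(adjustment_factor(c(0.5, 1)), "R_i")
})

test_that("property: AF <= 1, equals 1 iff at most one nonzero R_i, and is
           non-increasing as factors are appended", {
  set.seed(8)
  for (i in 1:50) {
    r <- runif(sample(2:8, 1), 0, 0.9)
    af <- adjustment_factor(r)$af
    expect_lte(af, 1)
    if (sum(r > 0) >= 2) expect_lt(af, 1)
    # appending a factor never increases AF
    expect_lte(adjustment_factor(c(r, runif(1, 0, 0.9)))$af, af + 1e-12)
  }
  expect_equal(adjustment_factor(c(0, 0.4, 0))$af, 1)
})

test_that("risk component and aggregation combine as published", {
  expect_equal(risk_component(c(100, -50), 1), 50)
  expect_equal(risk_component(c(100, 200), 0.28 / 0.30), 280)
  expect_equal(risk_component(numeric(0), 0.5), 0)

  agg <- aggregate_components(-733, 4376, 644, 4760)
  expect_equal(agg$nx_modeled, 4287)
  expect_equal(agg$percent_explained, 90.06, tolerance = 1e-3)
  expect_equal(round_half_away(agg$percent_explained, 1), 90.1)
  expect_equal(aggregate_components(0, 0, 0, 99)$nx_modeled, 0)
  expect_equal(aggregate_components(-100, 200, 0, 100)$percent_explained, 100)
  expect_error(aggregate_components(1, 2, 3, 0), "excess")

  expect_equal(round_half_away(share_of_total(1750, 4760), 1), 36.8)
  expect_equal(share_of_total(0, 4760), 0)
  expect_equal(round_half_away(share_of_total(-733, 4760), 1), -15.4)
})

test_that("conservation: modeled excess equals adjusted rows plus medication", {
  for (sd in c(2, 9, 31)) {
    tr <- generate_scenario(sd, n_factors = 6, n_meds = 2, pop_scale = 5e6)
    d <- decompose_scenario(tr$scenario)
    expect_equal(d$nx_modeled,
                 sum(d$contributions$nx_adjusted) + d$nx_med,
                 tolerance = 1e-9)
    expect_equal(d$nx_modeled, d$nx_med + d$nx_risk + d$nx_drugs,
                 tolerance = 1e-12)
  }
  d <- decompose_scenario(romania_scenario(), track = "published")
  expect_equal(d$nx_modeled, sum(d$contributions$nx_adjusted) + d$nx_med)
})

test_that("per-sex calculation first, then summation across sexes", {
  scn <- synthetic_truth(strong_scenario())$scenario
  d <- decompose_scenario(scn)
  ct <- d$contributions
  # every factor appears once per stratum and components are sex-sums
  expect_equal(nrow(ct), length(scn$factors) * length(scn$strata))
  by_cat <- tapply(ct$nx_adjusted, ct$category, sum)
  expect_equal(unname(by_cat[["drug_side_effect"]]), d$nx_drugs)
  expect_equal(sum(by_cat[c("risk_factor", "preventive")]), d$nx_risk)
})

test_that("published track aggregates reported rows and leaves AF unapplied", {
  d <- decompose_scenario(romania_scenario(), track = "published")
  expect_equal(d$nx_med, -733)
  expect_equal(d$nx_risk, 4376)
  expect_equal(d$nx_drugs, 644)
  expect_equal(d$nx_modeled, 4287)
  expect_true(any(grepl("not applied", d$notes)))
  # a scenario without annotations cannot run the published track
  expect_error(decompose_scenario(toy_scenario(), track = "published"),
               "reported_nx")
})
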