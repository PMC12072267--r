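test_that("default bounds use supplied CIs, else +/- 20% with clipping", {
  s <- list(stratum_record("women", 1e6, 1e6, 500, 700))
  f <- factor_spec("thr", "preventive", c(women = 0.9), c(women = 0.95),
                   c(women = 0.5),
                   bounds = list(relative_risk = list(
                     women = uncertainty_bounds(1.2, 1.6, "ci95"))))
  scn <- scenario(2008, 2018, s, list(f))
  db <- default_bounds(scn$factors[[1]])
  # supplied CI wins, unchanged
  expect_equal(db$relative_risk$women$low, 1.2)
  expect_equal(db$relative_risk$women$high, 1.6)
  expect_equal(db$relative_risk$women$source, "ci95")
  # +/- 20% fallback, prevalence clipped to [0, 1]
  expect_equal(db$prevalence_by$women$low, 0.72)
  expect_equal(db$prevalence_by$women$high, 1)
  expect_equal(db$prevalence_by$women$source, "pct20")

  f2 <- factor_spec("x", "risk_factor", c(women = 0.1), c(women = 0.2),
                    c(women = 0.5))
  scn2 <- scenario(2008, 2018, s, list(f2))
  db2 <- default_bounds(scn2$factors[[1]])
  expect_equal(db2$relative_risk$women$low, 0.4)
  expect_equal(db2$relative_risk$women$high, 0.6)

  md <- medication_spec("osteo", c(women = 100), c(women = 50), 0.9,
                        c(women = 2))
  scn3 <- scenario(2008, 2018, s, medications = list(md))
  dbm <- default_bounds(scn3$medications[[1]])
  expect_equal(dbm$rrr$high, 1)       # clipped to a proportion
  expect_equal(dbm$rrr$low, 0.72)
  expect_equal(dbm$osteo_rr$women$low, 1.6)
})

test_that("zero-width bounds collapse the extremes to the best estimate", {
  scn <- bounded_toy(width = 0)
  for (mode in c("enumeration", "monotone")) {
    sx <- extremes_analysis(scn, mode = mode)
    expect_equal(sx$min_explained, sx$best)
    expect_equal(sx$max_explained, sx$best)
  }
})

test_that("corner enumeration and monotone assembly agree on monotone toys", {
  sx_e <- extremes_analysis(toy_scenario(), mode = "enumeration")
  sx_m <- extremes_analysis(toy_scenario(), mode = "monotone")
  expect_equal(sx_e$min_explained, sx_m$min_explained)
  expect_equal(sx_e$max_explained, sx_m$max_explained)
  expect_lte(sx_e$min_explained, sx_e$best)
  expect_gte(sx_e$max_explained, sx_e$best)

  # randomized monotone scenarios: all RR > 1 and the prevalence increase is
  # large enough that it keeps its sign at every corner of the +/- 20% box
  # (otherwise the RR direction flips inside the box and no corner assembly
  # is exact). Without the overlap adjustment every parameter then enters
  # the output monotonically, so the two-corner monotone assembly equals
  # full corner enumeration; with the adjustment on, the monotone bracket
  # must at least be contained in the enumerated one (its corners are a
  # subset of the hypercube corners).
  set.seed(14)
  for (i in 1:5) {
    s <- list(stratum_record("women", 1e6, 1e6, 500, 900))
    fx <- lapply(1:2, function(j) {
      p_by <- runif(1, 0.1, 0.25)
      factor_spec(paste0("f", j), "risk_factor", c(women = p_by),
                  c(women = p_by + runif(1, 0.16, 0.3)),
                  c(women = runif(1, 1.2, 2)))
    })
    scn <- scenario(2008, 2018, s, fx)
    e <- extremes_analysis(scn, mode = "enumeration", adjustment = "none")
    m <- extremes_analysis(scn, mode = "monotone", adjustment = "none")
    expect_equal(e$min_explained, m$min_explained)
    expect_equal(e$max_explained, m$max_explained)

    e_af <- extremes_analysis(scn, mode = "enumeration")
    m_af <- extremes_analysis(scn, mode = "monotone")
    expect_gte(m_af$min_explained, e_af$min_explained - 1e-9)
    expect_lte(m_af$max_explained, e_af$max_explained + 1e-9)
  }
})

test_that("property: widening any parameter's bounds never narrows the range", {
  base <- bounded_toy(width = 0.05)
  wide <- bounded_toy(width = 0.15)
  b <- extremes_analysis(base, mode = "enumeration")
  w <- extremes_analysis(wide, mode = "enumeration")
  expect_lte(w$min_explained, b$min_explained)
  expect_gte(w$max_explained, b$max_explained)

  # widen a single parameter only
  one <- bounded_toy(width = 0.05)
  one$factors[[1]]$bounds$relative_risk$women <- uncertainty_bounds(1.2, 1.8)
  o <- extremes_analysis(one, mode = "enumeration")
  expect_lte(o$min_explained, b$min_explained)
  expect_gte(o$max_explained, b$max_explained)
})

test_that("enumeration refuses oversized hypercubes and suggests monotone", {
  expect_error(extremes_analysis(romania_scenario(), mode = "enumeration"),
               "monotone")
})

test_that("per-component ranges bracket each component's central value", {
  scn <- synthetic_truth(strong_scenario())$scenario
  sx <- extremes_analysis(scn, mode = "monotone")
  d <- decompose_scenario(scn)
  raw <- tapply(d$contributions$nx, d$contributions$factor, sum)
  for (nm in names(raw)) {
    row <- sx$per_component[sx$per_component$component == nm, ]
    expect_lte(row$low, raw[[nm]] + 1e-9)
    expect_gte(row$high, raw[[nm]] - 1e-9)
  }
  med_row <- sx$per_component[sx$per_component$type == "medication", ]
  expect_lte(med_row$low, d$nx_med + 1e-9)
  expect_gte(med_row$high, d$nx_med - 1e-9)
})

test_that("published reported ranges sum to a bracket containing the
           published best estimate", {
  scn <- romania_scenario()
  rng <- reported_extremes(scn)
  best <- decompose_scenario(scn, track = "published")$nx_modeled
  expect_equal(rng$min_explained, 3053)
  expect_equal(rng$max_explained, 5587)
  expect_lt(rng$min_explained, best)
  expect_gt(rng$max_explained, best)
  expect_error(reported_extremes(toy_scenario()), "reported_range")
})
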