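test_that("validation names the offending field", {
  s <- list(stratum_record("women", 1e6, 1e6, 10, 20))
  bad_prev <- factor_spec("smoking", "risk_factor",
                          c(women = 1.3), c(women = 0.2), c(women = 1.5))
  expect_error(scenario(2008, 2018, s, list(bad_prev)),
               "smoking.*prevalence_by")
  bad_rr <- factor_spec("smoking", "risk_factor",
                        c(women = 0.3), c(women = 0.2), c(women = -1))
  expect_error(scenario(2008, 2018, s, list(bad_rr)), "relative_risk")

  expect_error(stratum_record("women", -5, 1e6, 10, 20), "pop_by")
  expect_error(stratum_record("women", 1e6, 1e6, 10, 2e6), "observed_ey")
  expect_error(uncertainty_bounds(2, 1), "low")
  expect_error(scenario(2018, 2008, s), "end_year")
  expect_error(scenario(2008, 2018, list()), "stratum")

  bad_med <- medication_spec("osteo", c(women = 100), c(women = 50),
                             rrr = 1.4, osteo_rr = c(women = 6))
  expect_error(scenario(2008, 2018, s, medications = list(bad_med)), "rrr")
  bad_med2 <- medication_spec("osteo", c(women = 100), c(women = 50),
                              rrr = 0.5, osteo_rr = c(women = 0.5))
  expect_error(scenario(2008, 2018, s, medications = list(bad_med2)), "osteo_rr")
})

test_that("property: fuzzed out-of-range fields are all rejected", {
  s <- list(stratum_record("women", 1e6, 1e6, 10, 20))
  set.seed(11)
  for (i in 1:50) {
    p_by <- runif(1); p_ey <- runif(1); rr <- runif(1, 0.3, 3)
    which_bad <- sample(c("p_by", "p_ey", "rr", "bounds"), 1)
    bad_val <- if (which_bad == "rr") -runif(1) else 1 + runif(1, 0.01, 5)
    args <- list(p_by = p_by, p_ey = p_ey, rr = rr)
    bounds <- NULL
    if (which_bad == "bounds") {
      expect_error(uncertainty_bounds(2 + runif(1), 1), "low")
      next
    }
    args[[which_bad]] <- bad_val
    f <- factor_spec("f", "risk_factor", c(women = args$p_by),
                     c(women = args$p_ey), c(women = args$rr))
    expect_error(scenario(2008, 2018, s, list(f)))
  }
})

test_that("minimal scenarios are accepted", {
  scn <- scenario(2008, 2018, list(stratum_record("all", 1e5, 1e5, 5, 9)))
  expect_s3_class(scn, "hip_scenario")
  expect_length(scn$factors, 0)
})

test_that("unknown config keys are rejected by name", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("baseline_year: 2008", "end_year: 2018",
               "strata:", "  - sex: women", "    pop_by: 1000",
               "    pop_ey: 1000", "    observed_by: 1", "    observed_ey: 2",
               "typo_section: 1"), path)
  expect_error(read_scenario(path), "typo_section")

  writeLines(c("baseline_year: 2008", "end_year: 2018",
               "strata:", "  - sex: women", "    pop_by: 1000",
               "    pop_ey: 1000", "    observed_by: 1", "    observed_ey: 2",
               "factors:", "  - name: smoking", "    category: risk_factor",
               "    prevalence_by: 0.1", "    prevalence_ey: 0.2",
               "    relative_risk: 1.3", "    extra_key: 7"), path)
  expect_error(read_scenario(path), "extra_key")

  writeLines(c("baseline_year: 2008", "end_year: 2018"), path)
  expect_error(read_scenario(path), "strata")
  expect_error(read_scenario(file.path(tempdir(), "nope.yaml")), "exist")
})

test_that("scenarios round-trip through YAML field-by-field", {
  for (scn in list(romania_scenario(), strong_scenario(), bounded_toy())) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(scn, path)
    back <- read_scenario(path)
    expect_equal(back, scn)
  }
})

test_that("shared relative risks expand to all strata and stay flagged", {
  scn <- strong_scenario()
  rr <- scn$factors[["inactivity"]]$relative_risk
  expect_named(rr, c("women", "men"))
  expect_equal(unname(rr), c(1.8, 1.8), ignore_attr = TRUE)
  expect_true(attr(rr, "shared"))
  expect_false(attr(scn$factors[["smoking"]]$relative_risk, "shared"))
})

test_that("the packaged national scenario matches its published inputs", {
  scn <- romania_scenario()
  expect_length(scn$strata, 2)
  cats <- vapply(scn$factors, `[[`, "", "category")
  expect_equal(sum(cats != "drug_side_effect"), 5)
  expect_equal(sum(cats == "drug_side_effect"), 4)
  expect_length(scn$medications, 1)

  expect_equal(scn$strata[["women"]]$pop_ey, 11371000)
  expect_equal(scn$strata[["women"]]$observed_ey, 11512)
  expect_equal(sum(vapply(scn$strata, `[[`, 0, "observed_ey")), 16732)

  smoking <- scn$factors[["smoking"]]
  expect_equal(smoking$prevalence_by[["men"]], 0.268)
  expect_equal(smoking$prevalence_ey[["men"]], 0.404)
  expect_equal(smoking$relative_risk[["men"]], 1.47)

  gc <- scn$factors[["glucocorticoids"]]
  expect_equal(gc$prevalence_by[["women"]], 0.029)
  expect_equal(gc$prevalence_ey[["women"]], 0.047)
  expect_equal(gc$relative_risk[["women"]], 1.37)

  med <- scn$medications[[1]]
  expect_equal(sum(med$users_by), 8678)
  expect_equal(sum(med$users_ey), 3220)
  expect_equal(med$rrr, 0.53)
  expect_equal(unname(med$osteo_rr), c(6.4, 4.8), ignore_attr = TRUE)
})
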