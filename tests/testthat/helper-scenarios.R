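# Scenario builders shared across test files. Everything is generated in
# code; the only on-disk fixture is the packaged national scenario.

# minimal single-stratum toy: two harmful exposures with rising prevalence
toy_scenario <- function(options = list()) {
  s <- list(stratum_record("women", 1e6, 1e6, 500, 700))
  f1 <- factor_spec("exposure_a", "risk_factor",
                    c(women = 0.2), c(women = 0.4), c(women = 1.5))
  f2 <- factor_spec("exposure_b", "risk_factor",
                    c(women = 0.1), c(women = 0.3), c(women = 1.8))
  scenario(2008, 2018, s, list(f1, f2), options = options)
}

# two-sex scenario with decade-scale shifts in every exposure, mirroring the
# magnitude of national trends (large injected signal relative to Poisson
# noise at NE ~ 1e4); used to study recovery under sampling noise
strong_scenario <- function() {
  s <- list(stratum_record("women", 1.1e7, 1.1e7, 6600, 6600),
            stratum_record("men", 1.0e7, 1.0e7, 4000, 4000))
  fx <- list(
    factor_spec("obesity", "preventive",
                c(women = .55, men = .62), c(women = .58, men = .66),
                c(women = .66, men = .76)),
    factor_spec("inactivity", "risk_factor",
                c(women = .40, men = .44), c(women = .60, men = .64), 1.8),
    factor_spec("smoking", "risk_factor",
                c(women = .17, men = .27), c(women = .25, men = .42),
                c(women = 1.3, men = 1.47)),
    factor_spec("diabetes", "risk_factor",
                c(women = .04, men = .06), c(women = .08, men = .12), 1.27),
    factor_spec("sedatives", "drug_side_effect",
                c(women = .10, men = .06), c(women = .20, men = .14), 1.5))
  md <- list(medication_spec("bisphosphonates",
                             c(women = 7000, men = 2000),
                             c(women = 2500, men = 800),
                             0.53, c(women = 6.4, men = 4.8)))
  scenario(2008, 2018, s, fx, md)
}

# factor-only scenario whose every parameter carries explicit bounds
bounded_toy <- function(width = 0.1) {
  b <- function(x) uncertainty_bounds(x * (1 - width), x * (1 + width))
  f <- factor_spec("exposure_a", "risk_factor",
                   c(women = 0.2), c(women = 0.4), c(women = 1.5),
                   bounds = list(
                     prevalence_by = list(women = b(0.2)),
                     prevalence_ey = list(women = b(0.4)),
                     relative_risk = list(women = b(1.5))))
  s <- list(stratum_record("women", 1e6, 1e6, 500, 700))
  scenario(2008, 2018, s, list(f))
}
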