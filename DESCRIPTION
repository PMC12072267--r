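Package: hipimpact
Title: Deterministic Decomposition of Hip Fracture Incidence Trends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Explains the change in sex-stratified hip fracture counts between a
    baseline and an end year as the sum of contributions from osteoporosis
    medication uptake, population risk factors and preventive measures, and
    drugs with skeletal or fall-related side effects. Implements the
    HIP-IMPACT-style deterministic comparative risk assessment: expected
    end-year counts from baseline rates, population attributable risk fraction
    (PARF) changes per binary exposure, a cumulative-vs-additive overlap
    adjustment, and extremes (multidirectional) sensitivity analysis. Ships the
    Romania 2008-2018 national scenario and a synthetic-scenario generator with
    known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
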