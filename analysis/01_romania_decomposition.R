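#!/usr/bin/env Rscript
# Decompose the 2008-2018 change in Romanian hip-fracture counts.
#
# Applies the baseline (2008) sex-specific fracture rates to the 2018
# populations to get the expected counts, takes the observed-minus-expected
# excess, and attributes it to osteoporosis medication, population risk /
# preventive factors, and drugs with side effects — on both aggregation
# tracks (published per-row values vs recomputation from the equations).
# Writes the table CSVs, JSON summary and run log under results/romania/.

suppressPackageStartupMessages(library(hipimpact))

out_dir <- "results/romania"
scn <- romania_scenario()
res <- run_pipeline(scn, out_dir = out_dir)

exp0 <- res$tracks[[1]]$expectation
cat("== Baseline expectation ==\n")
print(exp0$strata[, c("sex", "rate_by", "rate_ey", "expected_ey", "excess")])
cat(sprintf("Expected %d fractures in 2018 at 2008 rates; %d observed;\n",
            exp0$totals$expected_ey, exp0$totals$observed_ey))
cat(sprintf("excess to explain: %d (women %d, men %d)\n",
            exp0$totals$excess, exp0$strata$excess[1], exp0$strata$excess[2]))
cat(sprintf("Goodness of fit of observed to expected: chi2(%d) = %.1f, p < 1e-10\n\n",
            exp0$gof$df, exp0$gof$chi2))

cat("== Decomposition, published track ==\n")
pub <- res$tracks$published
cat(sprintf("medication %+.0f (%.1f%%), risk factors %+.0f, drugs %+.0f (%.1f%%)\n",
            pub$nx_med, share_of_total(pub$nx_med, pub$excess),
            pub$nx_risk, pub$nx_drugs,
            share_of_total(pub$nx_drugs, pub$excess)))
cat(sprintf("modeled total: %+.0f = %.1f%% of the excess\n\n",
            pub$nx_modeled, pub$percent_explained))

cat("== Decomposition, equations track (from the tabulated inputs) ==\n")
eqn <- res$tracks$equations
cat(sprintf("medication %+.1f, risk factors %+.1f, drugs %+.1f => modeled %+.1f (%.1f%%)\n",
            eqn$nx_med, eqn$nx_risk, eqn$nx_drugs, eqn$nx_modeled,
            eqn$percent_explained))
cat(sprintf("overlap adjustment AF = %.4f (%s)\n", eqn$adjustment$af,
            eqn$adjustment$interpretation))
cat("The two tracks differ because the published per-row values rest on an\n")
cat("age-stratified expectation whose inputs were never published; the\n")
cat("equations track recomputes rows from the whole-population expectation.\n\n")

cat(sprintf("Artifacts written to %s:\n%s\n", out_dir,
            paste(" -", res$files, collapse = "\n")))
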