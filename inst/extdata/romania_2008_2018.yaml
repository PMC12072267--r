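# Romania 2008-2018 national hip-fracture scenario.
# Prevalences are proportions (published tables print percentages; divided by
# 100 here). Baseline rates per 10,000 are carried as printed (6.5, 3.87)
# because the published expected counts are keyed to those rounded values.
# reported_nx / reported_range carry the published per-row contributions for
# the "published" aggregation track; they are annotations, never recomputed.
baseline_year: 2008
end_year: 2018
strata:
  - sex: women
    pop_by: 11541500
    pop_ey: 11371000
    observed_by: 7513
    observed_ey: 11512
    rate_by: 6.5
  - sex: men
    pop_by: 11000500
    pop_ey: 11838000
    observed_by: 4266
    observed_ey: 5220
    rate_by: 3.87
factors:
  - name: bmi_over_25
    category: preventive
    prevalence_by: {women: 0.552, men: 0.619}
    prevalence_ey: {women: 0.611, men: 0.751}
    relative_risk: {women: 0.66, men: 0.76}
    reported_nx: {women: 1028, men: 722, total: 1750}
    reported_range: {low: 1486, high: 2057}
  - name: physical_activity
    category: preventive
    prevalence_by: {women: 0.581, men: 0.543}
    prevalence_ey: {women: 0.770, men: 0.682}
    relative_risk: 0.87
    reported_nx: {women: 964, men: 432, total: 1396}
    reported_range: {low: 1189, high: 1642}
  - name: smoking
    category: risk_factor
    prevalence_by: {women: 0.168, men: 0.268}
    prevalence_ey: {women: 0.217, men: 0.404}
    relative_risk: {women: 1.3, men: 1.47}
    reported_nx: {women: 427, men: 960, total: 1387}
    reported_range: {low: 1216, high: 1629}
  - name: type2_diabetes
    category: risk_factor
    prevalence_by: {women: 0.042, men: 0.065}
    prevalence_ey: {women: 0.061, men: 0.098}
    relative_risk: 1.27
    reported_nx: {women: 162, men: 172, total: 334}
    reported_range: {low: 278, high: 390}
  - name: total_hip_replacement
    category: preventive
    prevalence_by: {women: 0.051, men: 0.037}
    prevalence_ey: {women: 0.069, men: 0.053}
    relative_risk: 0.5
    reported_nx: {women: -316, men: -175, total: -491}
    reported_range: {low: -575, high: -415}
  - name: benzodiazepines
    category: drug_side_effect
    prevalence_by: {women: 0.131, men: 0.064}
    prevalence_ey: {women: 0.068, men: 0.037}
    relative_risk: 1.52
    reported_nx: {women: -437, men: -122, total: -559}
    reported_range: {low: -695, high: -471}
  - name: z_drugs
    category: drug_side_effect
    prevalence_by: {women: 0.215, men: 0.105}
    prevalence_ey: {women: 0.180, men: 0.091}
    relative_risk: 1.19
    reported_nx: {women: 295, men: 86, total: 381}
    reported_range: {low: 321, high: 446}
  - name: glucocorticoids
    category: drug_side_effect
    prevalence_by: {women: 0.029, men: 0.021}
    prevalence_ey: {women: 0.047, men: 0.037}
    relative_risk: 1.37
    reported_nx: {women: 316, men: 175, total: 491}
    reported_range: {low: 416, high: 542}
  - name: opioids
    category: drug_side_effect
    prevalence_by: {women: 0.164, men: 0.139}
    prevalence_ey: {women: 0.172, men: 0.150}
    relative_risk: 1.54
    reported_nx: {women: 177, men: 154, total: 331}
    reported_range: {low: 278, high: 389}
medications:
  - name: bisphosphonates
    users_by: {women: 6586, men: 2092}
    users_ey: {women: 2443, men: 777}
    rrr: 0.53
    osteo_rr: {women: 6.4, men: 4.8}
    reported_nx: {women: -614, men: -119, total: -733}
    reported_range: {low: -861, high: -622}
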