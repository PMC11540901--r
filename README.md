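# respstrat

Risk stratification and pharmaceutical-care planning for hospital
respiratory outpatients.

Hospital pharmacies follow outpatients with chronic respiratory disease —
severe asthma, COPD, cystic fibrosis, bronchiectasis, pulmonary
hypertension, idiopathic pulmonary fibrosis and other interstitial lung
diseases, nasal polyposis — whose care is complicated by inhaler
non-adherence, complex hospital-dispensed medicines and frequent
exacerbations. The Capacity pillar of the Capacity-Motivation-Opportunity
(CMO) pharmaceutical-care model answers the triage question: *which of
these patients need the most intensive pharmaceutical care?*

`respstrat` implements that pillar as a tested pipeline for
pharmacists, clinical epidemiologists and health-services researchers:

1. **Flag derivation** — 22 consensus variables in five groups
   (demographic 3, clinical 5, treatment-related 8, socio-sanitary 5,
   healthcare-resource use 1) are derived from raw records and instrument
   responses: Morisky-Green (4 items), TAI (inhaler adherence) and
   EQ-5D-5L (quality of life).
2. **Additive scoring** — each flagged variable `v` contributes its
   consensus weight `w_v`; the total is `S = Σ_v w_v · x_v` with `x_v ∈
   {0,1}` and the three BMI categories forming an exclusion set (at most
   one contributes). Maximum attainable `S` is 58.
3. **Cutoff calibration** — following the Kaiser Permanente pyramid, the
   top 10% of scores form priority level 1 and the next 30% level 2:
   `c1 = min{t : P(S ≥ t) ≤ 0.10}`, `c2 = min{t : P(S ≥ t) ≤ 0.40}`, with
   whole tie groups demoted. The shipped defaults are the tool's final
   multicenter calibration, `c1 = 32`, `c2 = 21`.
4. **Classification & overrides** — level 1 if `S ≥ c1` (or the patient is
   pregnant/postpartum or under 18 in an adult clinic — automatic level 1);
   level 2 if `c2 ≤ S < c1`; else level 3. Children 0–15, or under-18s in
   pediatric clinics, are routed to the separate pediatric model.
5. **Care plans** — cumulative interventions (pharmacotherapeutic
   monitoring 7, training/education 7, care coordination 6; level 1
   receives all 20), a monitoring-frequency map, telemedicine triage
   (group A: advanced digital skills; B: limited but adaptable) and
   per-disease teleconsultation recommendations.
6. **Synthetic cohorts** — a seeded generator with the development
   sample's marginal prevalences and a single-latent-factor correlation
   structure, plus a deterministic 201-record reconstruction of the
   published pilot accounting, so every stage is testable without patient
   data.

## Worked example

```r
library(respstrat)

# one patient: 70 y (2) + BMI 31 (3) + non-respiratory comorbidity (3)
# + 6 chronic drugs (3) + smoker (4) + 2 admissions (3)
rec <- validate_record(list(
  patient_id = "ex", age_years = 70, bmi_kg_m2 = 31,
  other_conditions_under_treatment = TRUE, chronic_drug_count = 6,
  smoker = TRUE, admissions_or_ed_visits_12mo = 2))
score_cohort(rec)$total_score
#> [1] 18

classify(18L, default_cutoffs())   # 21 <= S < 32 would be level 2
#> [1] 3

# the reconstructed 201-record development cohort through the pipeline
res <- run_pipeline(pilot_cohort())
res$summary
#> Cohort stratification summary
#>   records: 201 (pediatric-model excluded: 4, scored: 197)
#>   cutoffs: level 1 >= 32, level 2 >= 21 (default)
#>   level 1:   51 ( 25.9%)
#>   level 2:   26 ( 13.2%)
#>   level 3:  120 ( 60.9%)
#>   override-assigned level 1: 3
```

(The reconstruction matches the published per-group flag *counts* exactly
— e.g. 147/197 adults with polypharmacy — but only group-wise marginals
are published, so its joint structure, and hence its level split, is a
modeling artifact; see the vignette.)

Synthetic cohorts for simulation studies:

```r
cohort <- generate_cohort(cohort_spec(n = 1000, rho = 0.4, seed = 7))
summarize_cohort(classify(score_cohort(cohort)))
```

## Configuration

All tool definitions ship as editable YAML under `inst/extdata/`:
`weights.yaml` (the final consensus weight table), `cutoffs.yaml` (32/21),
`interventions.yaml`, `frequencies.yaml`,
`teleconsultation_recommendations.yaml`, `telepharmacy_tool_checklist.yaml`,
plus the cohort `column_dictionary.csv`. Loaders validate structural
invariants (22 variables in groups 3/5/8/5/1, non-negative integer
weights, catalog fields) and round-trip byte-identically through the
matching writers.
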