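Package: respstrat
Title: Risk Stratification and Pharmaceutical Care Planning for
    Respiratory Outpatients
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements the Capacity-pillar stratification tool of the
    Capacity-Motivation-Opportunity (CMO) pharmaceutical care model for
    hospital respiratory outpatients: derivation of 22 binary/categorical
    risk flags from patient records and instrument responses
    (Morisky-Green, TAI, EQ-5D-5L), additive weighted scoring with
    automatic priority-1 overrides and pediatric routing, percentile
    cutoff calibration following the Kaiser Permanente pyramid (10/30/60),
    three-level priority classification, cumulative care-plan and
    telemedicine triage mapping, and a seeded synthetic cohort generator
    with a single-latent-factor correlation structure for testing every
    stage without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
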