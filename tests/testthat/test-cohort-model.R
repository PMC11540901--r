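# record validation and flag derivation

test_that("well-formed records validate and malformed ones name the field", {
  rec <- record("p1", 70, bmi_kg_m2 = 31)
  expect_equal(rec$age_years, 70L)
  expect_true(is.na(rec$smoker))  # missing optional stays missing

  expect_error(record("p2", -3), "age_years out of range")
  expect_error(record("p3", 40, eq5d5l_levels = c(1, 1, 6, 1, 1)),
               "eq5d5l dimension 3")
  expect_error(record("p4", 40, chronic_drug_count = -1),
               "chronic_drug_count")
  expect_error(record("p5", 40, clinic_setting = "ward"), "clinic_setting")
  expect_error(record("p6", 40, respiratory_diagnoses = "influenza"),
               "unknown code 'influenza'")
  expect_error(record("p7", 40, morisky_items = c(TRUE, FALSE)),
               "all 4 items")
  expect_error(
    validate_cohort(data.frame(patient_id = "a", age_years = 1,
                               shoe_size = 43)),
    "unknown column")
  expect_silent(
    validate_cohort(data.frame(patient_id = "a", age_years = 1,
                               shoe_size = 43), permissive = TRUE))
})

test_that("threshold flags match a brute-force grid oracle", {
  # polypharmacy: > 5 drugs; healthcare use: >= 2 admissions/ED visits
  grid <- expand.grid(drugs = 0:12, adm = 0:6)
  cohort <- empty_cohort(nrow(grid))
  cohort$age_years <- 40L
  cohort$chronic_drug_count <- grid$drugs
  cohort$admissions_or_ed_visits_12mo <- grid$adm
  fl <- derive_flags(cohort)
  expect_equal(fl$polypharmacy, grid$drugs > 5)
  expect_equal(fl$hospitalisations_ed, grid$adm >= 2)
})

test_that("QoL impairment matches any-dimension oracle over all 5^5 vectors", {
  levels <- as.matrix(expand.grid(rep(list(1:5), 5)))
  cohort <- empty_cohort(nrow(levels))
  cohort$age_years <- 40L
  for (d in 1:5) cohort[[paste0("eq5d5l_", d)]] <- levels[, d]
  for (severe in 3:5) {
    fl <- derive_flags(cohort,
                       derivation_policy(eq5d_severe_level = severe))
    oracle <- apply(levels, 1, function(v) any(v >= severe))
    expect_equal(fl$qol_impairment, oracle,
                 info = paste("severe level", severe))
  }
})

test_that("Morisky-Green scoring agrees with the published rule on all 16 patterns", {
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  got <- score_morisky(patterns)
  # independent restatement: adherent iff no non-compliant answer
  oracle <- ifelse(rowSums(patterns) == 0, "adherent", "non-adherent")
  expect_equal(got, oracle)
  expect_equal(score_morisky(c(TRUE, FALSE, FALSE, FALSE)), "non-adherent")
  expect_true(is.na(score_morisky(c(TRUE, NA, FALSE, FALSE))))
  expect_error(score_morisky(c(TRUE, FALSE)), "4 answers")
})

test_that("adherence flag ORs the direct flag, Morisky and TAI sources", {
  cohort <- rbind(
    record("direct", 40, nonadherent_any_medication = TRUE),
    record("morisky", 40, nonadherent_any_medication = FALSE,
           morisky_items = c(TRUE, FALSE, FALSE, FALSE)),
    record("tai", 40, nonadherent_any_medication = FALSE, tai_total = 49),
    record("tai_good", 40, nonadherent_any_medication = FALSE,
           tai_total = 50),
    record("clean", 40, nonadherent_any_medication = FALSE,
           morisky_items = rep(FALSE, 4), tai_total = 50),
    record("unknown", 40))
  fl <- derive_flags(cohort)
  expect_equal(fl$adherence_lack, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # missing every adherence source: not flagged under the default policy,
  # and the record is less complete than one with the instruments filled
  expect_lt(fl$completeness[6], fl$completeness[5])
})

test_that("BMI categories are mutually exclusive and CF-specific", {
  cohort <- rbind(
    record("obese", 40, bmi_kg_m2 = 30),
    record("normal", 40, bmi_kg_m2 = 29.9),
    record("mal", 40, bmi_kg_m2 = 17, cystic_fibrosis = FALSE),
    record("cf_mal", 40, bmi_kg_m2 = 17, cystic_fibrosis = TRUE),
    record("border", 40, bmi_kg_m2 = 18.4),
    record("missing", 40))
  fl <- derive_flags(cohort)
  cats <- fl[c("obesity", "malnutrition", "cf_malnutrition")]
  expect_true(all(rowSums(cats) <= 1))
  expect_equal(fl$obesity, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$malnutrition, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$cf_malnutrition,
               c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("strict missing policy aborts naming patient and variable", {
  cohort <- record("p1", 40)  # everything optional missing
  expect_error(derive_flags(cohort, derivation_policy(missing = "strict")),
               "missing input for variable 'pregnancy' \\(patient p1\\)")
  # randomized property: derivation is deterministic and total
  set.seed(11)
  spec <- cohort_spec(60, rho = 0.4, seed = 77)
  g <- generate_cohort(spec)
  f1 <- derive_flags(g)
  f2 <- derive_flags(g)
  expect_identical(f1, f2)
  expect_false(anyNA(f1[setdiff(names(f1), "patient_id")]))
})

test_that("cohort CSV round-trips byte-identically", {
  g <- generate_cohort(cohort_spec(25, rho = 0.2, n_pediatric_clinic = 2,
                                   n_pregnant = 1, seed = 5))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(g, f1)
  back <- read_cohort_csv(f1)
  expect_equal(back, g, ignore_attr = TRUE)
  write_cohort_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
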