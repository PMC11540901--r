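# weight table structure and the additive scoring engine

test_that("default weight table has the published structure and maxima", {
  wt <- default_weight_table()
  expect_equal(length(unique(wt$variable_id)), 22)
  vars <- unique(wt[c("variable_id", "group")])
  expect_equal(as.vector(table(vars$group)[c(
    "demographic", "clinical", "treatment", "socio_sanitary",
    "healthcare_use")]), c(3, 5, 8, 5, 1))
  mx <- group_max_scores(wt)
  expect_equal(unname(mx[c("demographic", "clinical", "treatment",
                           "socio_sanitary", "healthcare_use", "total")]),
               c(5, 14, 20, 16, 3, 58))
})

test_that("malformed weight configs are rejected with a diagnosis", {
  wt <- default_weight_table()
  expect_error(validate_weight_table(wt[wt$variable_id != "naive_patient", ]),
               "group treatment has 7 of 8")
  bad <- wt; bad$points[2] <- -1L
  expect_error(validate_weight_table(bad), "non-negative")
  dup <- rbind(wt, wt[2, ])
  expect_error(validate_weight_table(dup), "duplicate weight entry")
})

test_that("weight table YAML config round-trips and matches the shipped file", {
  shipped <- system.file("extdata", "weights.yaml", package = "respstrat")
  wt <- load_weight_table(shipped)
  expect_equal(as.data.frame(wt), as.data.frame(default_weight_table()))
  f <- tempfile(fileext = ".yaml")
  write_weight_table(wt, f)
  expect_identical(readLines(f), readLines(shipped))
})

test_that("routing separates the pediatric model from the adult path", {
  cohort <- rbind(
    record("ped", 12, clinic_setting = "pediatric"),
    record("ped15", 15, clinic_setting = "adult"),
    record("teen_adult", 17, clinic_setting = "adult"),
    record("teen_ped", 17, clinic_setting = "pediatric"),
    record("adult", 40, clinic_setting = "adult"),
    record("no_setting", 16))
  r <- route_patient(cohort)
  expect_equal(r$routing,
               c("pediatric_model_excluded", "pediatric_model_excluded",
                 "adult_scored", "pediatric_model_excluded", "adult_scored",
                 "adult_scored"))
  expect_equal(r$pediatric_in_adult_clinic,
               c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("worked examples: empty, mixed, and maximal scores", {
  cohort <- rbind(
    record("none", 40, bmi_kg_m2 = 22, pregnant_or_postpartum = FALSE,
           chronic_drug_count = 0),
    # age >= 65 (2) + obesity (3) + non-respiratory comorbidity (3) +
    # polypharmacy (3) + smoking (4) + admissions (3) = 18
    record("mixed", 70, bmi_kg_m2 = 31,
           other_conditions_under_treatment = TRUE, chronic_drug_count = 6,
           smoker = TRUE, admissions_or_ed_visits_12mo = 2))
  res <- score_cohort(cohort)
  expect_equal(res$total_score, c(0L, 18L))

  # everything on: table maximum (obesity branch of the BMI set)
  all_on <- flag_frame(1)
  for (v in setdiff(names(all_on), "patient_id")) all_on[[v]] <- TRUE
  all_on$malnutrition <- FALSE
  all_on$cf_malnutrition <- FALSE
  expect_equal(score_flags(all_on)$total_score, 58L)
  # oracle: independent summation of per-variable maxima over the config
  wt <- default_weight_table()
  oracle_max <- sum(tapply(wt$points, wt$variable_id, max))
  expect_equal(score_flags(all_on)$total_score, oracle_max)
})

test_that("engine totals equal brute-force dot products over 2^10 patterns", {
  w <- default_weights_vector()
  # a 10-variable subset avoiding the BMI exclusion set (tested separately)
  vars <- c("age_65_plus", "respiratory_comorbidity", "mental_disorders",
            "cognitive_impairment", "adherence_lack", "high_alert_medicines",
            "polypharmacy", "tobacco", "qol_impairment",
            "hospitalisations_ed")
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 10)))
  colnames(patterns) <- vars
  fl <- flag_frame(nrow(patterns))
  for (v in vars) fl[[v]] <- patterns[, v]
  got <- score_flags(fl)$total_score
  expect_equal(got, as.integer(patterns %*% w[vars]))
})

test_that("adding a flag never decreases the total (monotonicity)", {
  set.seed(42)
  triggers <- setdiff(names(flag_frame(1)), "patient_id")
  for (rep in 1:50) {
    base <- flag_frame(1)
    on <- sample(triggers, sample(0:8, 1))
    for (v in on) base[[v]] <- TRUE
    s0 <- score_flags(base)$total_score
    flip <- sample(setdiff(triggers, on), 1)
    base[[flip]] <- TRUE
    expect_gte(score_flags(base)$total_score, s0)
  }
})

test_that("BMI exclusion set awards only the heaviest triggered entry", {
  # CF patient with BMI 17: both malnutrition rows trigger, 3 not 3+1
  both <- flag_frame(1, malnutrition = TRUE, cf_malnutrition = TRUE)
  res <- score_flags(both)
  expect_equal(res$bmi, 3L)
  expect_equal(res$total_score, 3L)
  # through the full derivation path
  rec <- record("cf", 40, bmi_kg_m2 = 17, cystic_fibrosis = TRUE)
  expect_equal(score_cohort(rec)$bmi, 3L)
  mal_only <- flag_frame(1, malnutrition = TRUE)
  expect_equal(score_flags(mal_only)$total_score, 1L)
})

test_that("overrides direct classification without altering the score", {
  cohort <- rbind(
    record("pregnant", 30, pregnant_or_postpartum = TRUE),
    record("teen", 17, clinic_setting = "adult"),
    record("both", 17, clinic_setting = "adult",
           pregnant_or_postpartum = TRUE),
    record("plain", 40))
  res <- score_cohort(cohort)
  expect_equal(res$override, c("pregnancy", "pediatric_in_adult_clinic",
                               "pediatric_in_adult_clinic", "none"))
  expect_equal(res$total_score, rep(0L, 4))
  lv <- classify(res, default_cutoffs())
  expect_equal(lv$priority_level, c(1L, 1L, 1L, 3L))
})
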