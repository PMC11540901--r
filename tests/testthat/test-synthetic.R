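# synthetic cohort generator and the reconstructed development sample

test_that("generation is reproducible and edge cases are injected exactly", {
  spec <- cohort_spec(80, rho = 0.5, n_pediatric_clinic = 3,
                      n_pediatric_adult_clinic = 2, n_pregnant = 4,
                      seed = 123)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort_csv(g1, f1); write_cohort_csv(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  r <- route_patient(g1)
  expect_equal(sum(r$routing == "pediatric_model_excluded"), 3)
  expect_equal(sum(r$pediatric_in_adult_clinic), 2)
  expect_equal(sum(g1$pregnant_or_postpartum), 4)
  expect_equal(nrow(generate_cohort(cohort_spec(0))), 0)
  expect_error(cohort_spec(3, n_pregnant = 4), "exceed")
  # a different seed changes the draw
  expect_false(identical(generate_cohort(spec, seed = 124), g1))
})

test_that("generated raw fields are consistent with their flags", {
  g <- generate_cohort(cohort_spec(400, rho = 0.4, seed = 9))
  fl <- derive_flags(g)
  expect_equal(fl$polypharmacy, g$chronic_drug_count > 5)
  expect_equal(fl$age_65_plus, g$age_years >= 65)
  expect_equal(fl$obesity, g$bmi_kg_m2 >= 30)
  # BMI categories exclusive; no CF-malnutrition by construction
  expect_true(all(rowSums(fl[c("obesity", "malnutrition",
                               "cf_malnutrition")]) <= 1))
  expect_false(any(fl$cf_malnutrition))
  expect_true(all(fl$completeness == 1))
})

test_that("marginal prevalences are recovered within binomial error", {
  n <- 4000
  for (rho in c(0, 0.6)) {
    g <- generate_cohort(cohort_spec(n, rho = rho, seed = 31))
    fl <- derive_flags(g)
    prev <- default_prevalences()
    emp <- colMeans(fl[names(prev)])
    se <- sqrt(prev * (1 - prev) / n)
    expect_true(all(abs(emp - prev) <= 4 * se),
                info = paste("rho =", rho))
  }
})

test_that("the latent factor induces non-negative pairwise association", {
  g <- generate_cohort(cohort_spec(4000, rho = 0.5, seed = 17))
  fl <- derive_flags(g)
  # malnutrition is deliberately off-factor (kept exclusive of obesity), so
  # association is checked over the factor-loaded flags
  vars <- setdiff(names(default_prevalences()), "malnutrition")
  m <- as.matrix(fl[vars]) * 1
  cm <- suppressWarnings(stats::cor(m))
  off <- cm[upper.tri(cm)]
  expect_true(all(off[!is.na(off)] > -0.05))
  expect_gt(mean(off, na.rm = TRUE), 0.05)
})

test_that("stronger correlation widens the score distribution", {
  v <- vapply(c(0, 0.8), function(rho) {
    g <- generate_cohort(cohort_spec(4000, rho = rho, seed = 55))
    stats::var(score_cohort(g)$total_score)
  }, numeric(1))
  expect_gt(v[2], v[1])
})

test_that("reconstructed development cohort matches the published accounting", {
  coh <- pilot_cohort(include_group = TRUE)
  group <- coh$pilot_group
  coh <- coh[setdiff(names(coh), "pilot_group")]
  expect_equal(nrow(coh), 201)
  r <- route_patient(coh)
  expect_equal(sum(r$routing == "adult_scored"), 197)
  expect_equal(sum(r$pediatric_in_adult_clinic), 3)
  expect_equal(sum(coh$pregnant_or_postpartum, na.rm = TRUE), 0)

  fl <- derive_flags(coh)
  adult <- r$routing == "adult_scored"
  expect_equal(sum(fl$polypharmacy[adult]), 147)

  # every published per-group flag count is reproduced exactly
  counts <- pilot_group_counts()
  for (g in c("P1", "P2", "P3")) {
    in_g <- group == g
    got <- vapply(counts$flag, function(v) sum(fl[[v]][in_g]), integer(1))
    expect_equal(unname(got), counts[[tolower(g)]], info = g)
  }
  # reconstruction is deterministic
  expect_identical(pilot_cohort(), pilot_cohort())
})

test_that("metadata sidecar regenerates the cohort", {
  g <- generate_cohort(cohort_spec(30, rho = 0.2, seed = 77))
  f <- tempfile(fileext = ".yaml")
  write_cohort_metadata(g, f)
  meta <- yaml::read_yaml(f)
  spec2 <- cohort_spec(meta$n, prevalence = unlist(meta$prevalence),
                       rho = meta$rho,
                       n_pediatric_clinic = meta$n_pediatric_clinic,
                       n_pediatric_adult_clinic =
                         meta$n_pediatric_adult_clinic,
                       n_pregnant = meta$n_pregnant, seed = meta$seed)
  expect_equal(generate_cohort(spec2), g, ignore_attr = TRUE)
})
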