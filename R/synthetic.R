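# seeded synthetic cohorts: latent-factor correlated flags + raw-field fill

#' Default flag prevalences for the synthetic generator
#'
#' Marginal prevalences of the stratification flags in the 197-adult
#' multicenter development sample (total column of its descriptive table),
#' e.g. polypharmacy 0.75, non-respiratory comorbidity 0.71, complex
#' hospital medicines 0.69.
#'
#' @return Named numeric vector over the 22 scored flag ids (pregnancy is
#'   handled as an edge-case count, not a prevalence).
#' @export
default_prevalences <- function() {
  c(age_65_plus = 0.46, obesity = 0.22, malnutrition = 0.02,
    respiratory_comorbidity = 0.37, non_respiratory_comorbidity = 0.71,
    mental_disorders = 0.11, cognitive_impairment = 0.07, severity = 0.54,
    adherence_lack = 0.36, worsening_drugs = 0.11,
    high_alert_medicines = 0.46, objectives_not_reached = 0.34,
    polypharmacy = 0.75, complex_medicines = 0.69, naive_patient = 0.36,
    therapy_changes = 0.52, tobacco = 0.10, alcohol_drugs = 0.02,
    occupational_exposure = 0.07, low_ses = 0.04, qol_impairment = 0.49,
    hospitalisations_ed = 0.36)
}

#' Specify a synthetic cohort
#'
#' @param n Cohort size.
#' @param prevalence Named vector of marginal flag prevalences; defaults to
#'   [default_prevalences()].
#' @param rho Latent-factor correlation strength in `[0, 1)`: each flag is
#'   thresholded on `sqrt(rho) * z + sqrt(1 - rho) * noise` with a shared
#'   per-patient severity factor `z`, so marginals are preserved while
#'   pairwise associations grow with `rho`.
#' @param n_pediatric_clinic Pediatric patients seen in pediatric clinics
#'   (routing-excluded edge cases), injected exactly.
#' @param n_pediatric_adult_clinic Under-18 patients seen in adult clinics
#'   (automatic level-1 overrides), injected exactly.
#' @param n_pregnant Pregnant/postpartum records, injected exactly.
#' @param seed Integer seed stored with the spec; [generate_cohort()] is
#'   reproducible for identical spec + seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence = default_prevalences(), rho = 0,
                        n_pediatric_clinic = 0L,
                        n_pediatric_adult_clinic = 0L, n_pregnant = 0L,
                        seed = 1L) {
  stopifnot(is_scalar_int(n), n >= 0)
  if (!all(names(default_prevalences()) %in% names(prevalence))) {
    stop_input("prevalence must name every scored flag; see ",
               "default_prevalences()")
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop_input("prevalences must lie in [0, 1]")
  }
  if (!(length(rho) == 1 && rho >= 0 && rho < 1)) {
    stop_input("rho must lie in [0, 1)")
  }
  edges <- c(n_pediatric_clinic, n_pediatric_adult_clinic, n_pregnant)
  stopifnot(all(vapply(edges, is_scalar_int, logical(1))), all(edges >= 0))
  if (sum(edges) > n) {
    stop_input("edge-case counts (", sum(edges), ") exceed cohort size ", n)
  }
  structure(list(n = as.integer(n),
                 prevalence = prevalence[names(default_prevalences())],
                 rho = rho,
                 n_pediatric_clinic = as.integer(n_pediatric_clinic),
                 n_pediatric_adult_clinic = as.integer(
                   n_pediatric_adult_clinic),
                 n_pregnant = as.integer(n_pregnant),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# raw-field fill from a flag matrix; convenience values, not epidemiology
.fill_fields <- function(cohort, fl) {
  n <- nrow(cohort)
  cohort$age_years <- ifelse(fl[, "age_65_plus"],
                             sample(65:90, n, replace = TRUE),
                             sample(18:64, n, replace = TRUE))
  cohort$clinic_setting <- rep("adult", n)
  cohort$pregnant_or_postpartum <- rep(FALSE, n)
  bmi <- round(stats::runif(n, 18.5, 29.9), 1)
  bmi[fl[, "obesity"]] <- round(stats::runif(sum(fl[, "obesity"]), 30, 45), 1)
  bmi[fl[, "malnutrition"]] <- round(
    stats::runif(sum(fl[, "malnutrition"]), 15, 18.3), 1)
  cohort$bmi_kg_m2 <- bmi

  # diagnoses: one disease, two when multiple respiratory conditions are
  # under treatment; cystic fibrosis is kept away from low-BMI records so
  # the malnutrition marginal is exact (CF-malnutrition would supersede it)
  pool <- disease_catalog()
  dx <- character(n)
  for (i in seq_len(n)) {
    p <- if (bmi[i] < 18.4) setdiff(pool, "cystic_fibrosis") else pool
    k <- if (fl[i, "respiratory_comorbidity"]) 2 else 1
    dx[i] <- paste(sample(p, k), collapse = ";")
  }
  cohort$respiratory_diagnoses <- dx
  cohort$cystic_fibrosis <- grepl("cystic_fibrosis", dx, fixed = TRUE)

  direct <- c(multiple_respiratory_conditions = "respiratory_comorbidity",
              other_conditions_under_treatment = "non_respiratory_comorbidity",
              mental_disorder_treated = "mental_disorders",
              cognitive_impairment = "cognitive_impairment",
              severe_or_oxygen_therapy = "severity",
              nonadherent_any_medication = "adherence_lack",
              drug_worsening_respiratory = "worsening_drugs",
              high_alert_medicine = "high_alert_medicines",
              objectives_not_reached = "objectives_not_reached",
              complex_hospital_medicine = "complex_medicines",
              naive_hospital_medication = "naive_patient",
              therapy_change_6mo = "therapy_changes",
              smoker = "tobacco",
              alcohol_or_drug_use = "alcohol_drugs",
              occupational_particulate_exposure = "occupational_exposure",
              low_socioeconomic_status = "low_ses")
  for (f in names(direct)) cohort[[f]] <- fl[, direct[[f]]]

  cohort$chronic_drug_count <- ifelse(fl[, "polypharmacy"],
                                      sample(6:12, n, replace = TRUE),
                                      sample(0:5, n, replace = TRUE))
  cohort$admissions_or_ed_visits_12mo <- ifelse(
    fl[, "hospitalisations_ed"],
    sample(2:6, n, replace = TRUE), sample(0:1, n, replace = TRUE))

  # instruments consistent with the adherence flag: non-adherent records
  # fail one random Morisky item and score below the TAI threshold
  nonadh <- fl[, "adherence_lack"]
  mk <- matrix(FALSE, n, 4)
  mk[cbind(which(nonadh), sample(1:4, sum(nonadh), replace = TRUE))] <- TRUE
  for (j in 1:4) cohort[[paste0("morisky_", j)]] <- mk[, j]
  cohort$tai_total <- ifelse(nonadh, sample(35:49, n, replace = TRUE), 50L)

  eq <- matrix(sample(1:3, 5 * n, replace = TRUE), n, 5)
  bad <- which(fl[, "qol_impairment"])
  eq[cbind(bad, sample(1:5, length(bad), replace = TRUE))] <-
    sample(4:5, length(bad), replace = TRUE)
  for (d in 1:5) cohort[[paste0("eq5d5l_", d)]] <- eq[, d]

  cohort$digital_skill <- sample(c("advanced", "limited", "none"), n,
                                 replace = TRUE, prob = c(0.35, 0.40, 0.25))
  cohort
}

#' Generate a synthetic cohort
#'
#' Draws the 22 stratification flags from a single-latent-factor threshold
#' model (Gaussian-copula style): per patient a severity factor
#' `z ~ N(0, 1)` is shared across flags, flag `v` fires when
#' `sqrt(rho) * z + sqrt(1 - rho) * e_v` exceeds the normal quantile that
#' preserves its marginal prevalence. Malnutrition uses an independent
#' uniform with probability `p / (1 - p_obesity)` and is suppressed on
#' obese records, which keeps its marginal exact and the BMI categories
#' mutually exclusive. Raw fields (ages, BMI, drug counts, admissions,
#' instrument responses, diagnoses) are filled consistently with the flags,
#' then the requested edge cases overwrite the leading records exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed override; defaults to `spec$seed`.
#' @return A validated cohort data frame with attributes `spec`, `seed` and
#'   `generator_version`. Identical spec + seed gives identical records.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(50, seed = 7))
#' mean(derive_flags(cohort)$polypharmacy)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  cohort <- with_seed(seed, {
    prev <- spec$prevalence
    copula_flags <- setdiff(names(prev), "malnutrition")
    z <- stats::rnorm(n)
    fl <- matrix(FALSE, n, length(prev),
                 dimnames = list(NULL, names(prev)))
    for (v in copula_flags) {
      u <- sqrt(spec$rho) * z + sqrt(1 - spec$rho) * stats::rnorm(n)
      fl[, v] <- u > stats::qnorm(1 - prev[[v]])
    }
    p_mal <- prev[["malnutrition"]] / (1 - prev[["obesity"]])
    fl[, "malnutrition"] <- stats::runif(n) < p_mal & !fl[, "obesity"]

    cohort <- empty_cohort(n)
    if (n > 0) cohort <- .fill_fields(cohort, fl)

    i <- 0L
    if (spec$n_pediatric_clinic > 0) {
      idx <- i + seq_len(spec$n_pediatric_clinic)
      cohort$age_years[idx] <- sample(0:15, length(idx), replace = TRUE)
      cohort$clinic_setting[idx] <- "pediatric"
      i <- i + spec$n_pediatric_clinic
    }
    if (spec$n_pediatric_adult_clinic > 0) {
      idx <- i + seq_len(spec$n_pediatric_adult_clinic)
      cohort$age_years[idx] <- sample(16:17, length(idx), replace = TRUE)
      cohort$clinic_setting[idx] <- "adult"
      i <- i + spec$n_pediatric_adult_clinic
    }
    if (spec$n_pregnant > 0) {
      idx <- i + seq_len(spec$n_pregnant)
      cohort$age_years[idx] <- sample(18:45, length(idx), replace = TRUE)
      cohort$pregnant_or_postpartum[idx] <- TRUE
    }
    cohort
  })
  cohort <- validate_cohort(cohort)
  attr(cohort, "spec") <- spec
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "generator_version") <- "1"
  cohort
}

#' Write the generation metadata sidecar
#'
#' Records spec, seed and generator version next to a generated CSV so a
#' cohort can be regenerated byte-identically.
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Sidecar path (conventionally `<cohort>.meta.yaml`).
#' @return `path`, invisibly.
#' @export
write_cohort_metadata <- function(cohort, path) {
  spec <- attr(cohort, "spec")
  if (is.null(spec)) stop_input("cohort carries no generation metadata")
  yaml::write_yaml(list(
    n = spec$n, prevalence = as.list(spec$prevalence), rho = spec$rho,
    n_pediatric_clinic = spec$n_pediatric_clinic,
    n_pediatric_adult_clinic = spec$n_pediatric_adult_clinic,
    n_pregnant = spec$n_pregnant, seed = attr(cohort, "seed"),
    generator_version = attr(cohort, "generator_version")), path)
  invisible(path)
}

#' Per-priority-group flag counts of the development sample
#'
#' The published descriptive table of the 201-patient multicenter pilot:
#' flag counts for the 197 scored adults split by assigned priority group
#' (P1 n=21, P2 n=64, P3 n=112); the remaining 4 records are pediatric
#' patients seen in pediatric clinics, excluded from the adult tool.
#'
#' @return Data frame with columns `flag`, `p1`, `p2`, `p3`.
#' @export
pilot_group_counts <- function() {
  utils::read.csv(extdata("pilot_group_counts.csv"), stringsAsFactors = FALSE)
}

#' Reconstruct the development-sample cohort
#'
#' A deterministic 201-record stand-in for the (unavailable) pilot data:
#' 4 pediatric-clinic records plus 197 adult-path records whose flag counts
#' match [pilot_group_counts()] exactly within each priority group,
#' including the 3 under-18 patients seen in adult clinics and 0 pregnant
#' records. Only group-wise marginals are published, so the joint structure
#' is synthesized with a fixed fill order (for each flag, the first `k`
#' records of the group are flagged); this cohort is a worked-example
#' fixture, not a recovery of the real patients or their score
#' distribution.
#'
#' @param include_group Add a `pilot_group` column (`P1`/`P2`/`P3`/
#'   `pediatric`) recording the published group assignment? Off by default
#'   so the result matches the cohort column dictionary.
#' @return A validated cohort data frame (plus `pilot_group` if requested).
#' @export
#' @examples
#' summarize_cohort(classify(score_cohort(pilot_cohort())))
pilot_cohort <- function(include_group = FALSE) {
  counts <- pilot_group_counts()
  sizes <- c(P1 = 21L, P2 = 64L, P3 = 112L)
  groups <- list()
  for (g in names(sizes)) {
    ng <- sizes[[g]]
    k <- counts[[tolower(g)]]
    names(k) <- counts$flag
    df <- empty_cohort(ng)
    on_first <- function(kk) c(rep(TRUE, kk), rep(FALSE, ng - kk))

    # overrides live in P1: the published P1 column counts 12 records aged
    # >= 65; the 3 under-18-in-adult-clinic overrides take the tail slots
    df$age_years <- ifelse(on_first(k[["age_65_plus"]]), 70L, 45L)
    if (g == "P1") df$age_years[(ng - 2):ng] <- c(16L, 17L, 17L)
    df$clinic_setting <- "adult"
    df$pregnant_or_postpartum <- FALSE
    df$cystic_fibrosis <- FALSE

    # BMI categories are exclusive: malnourished first, then obese
    bmi <- rep(24, ng)
    n_mal <- k[["malnutrition"]]
    n_obe <- k[["obesity"]]
    if (n_mal > 0) bmi[seq_len(n_mal)] <- 17
    if (n_obe > 0) bmi[n_mal + seq_len(n_obe)] <- 32
    df$bmi_kg_m2 <- bmi

    df$respiratory_diagnoses <- ifelse(
      on_first(k[["respiratory_comorbidity"]]), "asthma;copd", "copd")
    df$multiple_respiratory_conditions <-
      on_first(k[["respiratory_comorbidity"]])
    df$other_conditions_under_treatment <-
      on_first(k[["non_respiratory_comorbidity"]])
    df$mental_disorder_treated <- on_first(k[["mental_disorders"]])
    df$cognitive_impairment <- on_first(k[["cognitive_impairment"]])
    df$severe_or_oxygen_therapy <- on_first(k[["severity"]])
    df$nonadherent_any_medication <- on_first(k[["adherence_lack"]])
    df$drug_worsening_respiratory <- on_first(k[["worsening_drugs"]])
    df$high_alert_medicine <- on_first(k[["high_alert_medicines"]])
    df$objectives_not_reached <- on_first(k[["objectives_not_reached"]])
    df$chronic_drug_count <- ifelse(on_first(k[["polypharmacy"]]), 8L, 2L)
    df$complex_hospital_medicine <- on_first(k[["complex_medicines"]])
    df$naive_hospital_medication <- on_first(k[["naive_patient"]])
    df$therapy_change_6mo <- on_first(k[["therapy_changes"]])
    df$smoker <- on_first(k[["tobacco"]])
    df$alcohol_or_drug_use <- on_first(k[["alcohol_drugs"]])
    df$occupational_particulate_exposure <-
      on_first(k[["occupational_exposure"]])
    df$low_socioeconomic_status <- on_first(k[["low_ses"]])
    df$admissions_or_ed_visits_12mo <-
      ifelse(on_first(k[["hospitalisations_ed"]]), 2L, 0L)
    for (j in 1:4) df[[paste0("morisky_", j)]] <- FALSE
    df$tai_total <- 50L
    qol <- on_first(k[["qol_impairment"]])
    for (d in 1:5) df[[paste0("eq5d5l_", d)]] <- 1L
    df$eq5d5l_4 <- ifelse(qol, 4L, 1L)
    df$digital_skill <- "limited"
    df$patient_id <- paste0(tolower(g), "_", seq_len(ng))
    df$pilot_group <- g
    groups[[g]] <- df
  }

  ped <- empty_cohort(4L)
  ped$patient_id <- paste0("ped_", 1:4)
  ped$age_years <- c(6L, 9L, 11L, 14L)
  ped$clinic_setting <- "pediatric"
  ped$pilot_group <- "pediatric"

  cohort <- rbind(groups$P1, groups$P2, groups$P3, ped)
  rownames(cohort) <- NULL
  grp <- cohort$pilot_group
  cohort$pilot_group <- NULL
  cohort <- validate_cohort(cohort)
  if (include_group) cohort$pilot_group <- grp
  cohort
}
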