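# derivation of the 22 stratification flags from raw records

#' Flag-derivation policy
#'
#' Controls how raw fields map to stratification flags.
#'
#' @param missing `"absent"` (default): a variable whose inputs are all
#'   missing is not flagged (contributes 0 points) and the record's
#'   `completeness` drops below 1. `"strict"`: missing inputs abort with an
#'   error naming the patient and variable.
#' @param tai_threshold Minimum TAI total counted as good adherence
#'   (default 50, the standard TAI-10 rule: non-adherent iff total < 50).
#' @param eq5d_severe_level Minimum EQ-5D-5L dimension level counted as
#'   severe impairment (default 4 = severe/extreme problems).
#' @return A list of class `derivation_policy`.
#' @export
derivation_policy <- function(missing = c("absent", "strict"),
                              tai_threshold = 50L,
                              eq5d_severe_level = 4L) {
  missing <- match.arg(missing)
  stopifnot(is_scalar_int(tai_threshold),
            is_scalar_int(eq5d_severe_level),
            eq5d_severe_level >= 1, eq5d_severe_level <= 5)
  structure(list(missing = missing,
                 tai_threshold = as.integer(tai_threshold),
                 eq5d_severe_level = as.integer(eq5d_severe_level)),
            class = "derivation_policy")
}

#' Score the 4-item Morisky-Green(-Levine) adherence test
#'
#' Each item is `TRUE` when the patient gave the non-compliant answer
#' (polarity fixed by the schema). A patient is adherent iff all four
#' answers are compliant.
#'
#' @param items Logical vector of length 4, or a 4-column logical matrix
#'   (one row per patient).
#' @return `"adherent"`/`"non-adherent"` per patient; `NA` when any item is
#'   missing (missing-instrument signal).
#' @export
#' @examples
#' score_morisky(c(FALSE, FALSE, FALSE, FALSE))
#' score_morisky(c(TRUE, FALSE, FALSE, FALSE))
score_morisky <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    if (ncol(items) != 4) stop_input("morisky items must have 4 columns")
    complete <- rowSums(is.na(items)) == 0
    out <- ifelse(rowSums(items, na.rm = FALSE) == 0,
                  "adherent", "non-adherent")
    out[!complete] <- NA
    return(out)
  }
  if (length(items) != 4) {
    stop_input("morisky items: 4 answers required, got ", length(items))
  }
  if (anyNA(items)) return(NA_character_)
  if (any(as.logical(items))) "non-adherent" else "adherent"
}

#' Derive the stratification flags for a cohort
#'
#' Maps validated raw records to the 22-variable flag set:
#' * `age_65_plus`: `age_years >= 65`
#' * BMI category: `obesity` (BMI >= 30), `malnutrition` (BMI < 18.4,
#'   no cystic fibrosis), `cf_malnutrition` (BMI < 18.4 with cystic
#'   fibrosis) — mutually exclusive
#' * `polypharmacy`: more than 5 chronic drugs
#' * `hospitalisations_ed`: >= 2 admissions and/or emergency visits in the
#'   last 12 months for respiratory decompensation
#' * `qol_impairment`: any EQ-5D-5L dimension at or above
#'   `policy$eq5d_severe_level`
#' * `adherence_lack`: non-adherent to any medication by the direct flag,
#'   the Morisky-Green test, or TAI total below `policy$tai_threshold`
#'   (OR across available sources)
#' * remaining variables are taken from their input flags.
#'
#' @param cohort A validated cohort (see [validate_cohort()]).
#' @param policy A [derivation_policy()].
#' @return A data frame with `patient_id`, one logical column per flag id,
#'   and `completeness` (fraction of the 22 variables derivable from
#'   non-missing inputs).
#' @export
derive_flags <- function(cohort, policy = derivation_policy()) {
  stopifnot(inherits(policy, "derivation_policy"))
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  strict <- policy$missing == "strict"

  miss <- function(variable, available) {
    if (strict && any(!available)) {
      stop_input(sprintf(
        "missing input for variable '%s' (patient %s) under strict policy",
        variable, cohort$patient_id[which(!available)[1]]))
    }
    available
  }
  # resolve a derived logical under the policy; records number of derivable
  derivable <- matrix(TRUE, n, 0)
  resolve <- function(variable, value, available) {
    available <- miss(variable, available)
    derivable <<- cbind(derivable, available)
    value & available & !is.na(value)
  }

  flags <- data.frame(patient_id = cohort$patient_id,
                      stringsAsFactors = FALSE)

  flags$pregnancy <- resolve("pregnancy", cohort$pregnant_or_postpartum,
                             !is.na(cohort$pregnant_or_postpartum))
  flags$age_65_plus <- resolve("age", cohort$age_years >= 65, rep(TRUE, n))

  bmi_known <- !is.na(cohort$bmi_kg_m2)
  cf <- !is.na(cohort$cystic_fibrosis) & cohort$cystic_fibrosis
  low <- bmi_known & cohort$bmi_kg_m2 < 18.4
  bmi_avail <- miss("bmi", bmi_known)
  derivable <- cbind(derivable, bmi_avail)
  flags$obesity <- bmi_known & cohort$bmi_kg_m2 >= 30
  flags$malnutrition <- low & !cf
  flags$cf_malnutrition <- low & cf

  direct <- c(respiratory_comorbidity = "multiple_respiratory_conditions",
              non_respiratory_comorbidity = "other_conditions_under_treatment",
              mental_disorders = "mental_disorder_treated",
              cognitive_impairment = "cognitive_impairment",
              severity = "severe_or_oxygen_therapy",
              worsening_drugs = "drug_worsening_respiratory",
              high_alert_medicines = "high_alert_medicine",
              objectives_not_reached = "objectives_not_reached",
              complex_medicines = "complex_hospital_medicine",
              naive_patient = "naive_hospital_medication",
              therapy_changes = "therapy_change_6mo",
              tobacco = "smoker",
              alcohol_drugs = "alcohol_or_drug_use",
              occupational_exposure = "occupational_particulate_exposure",
              low_ses = "low_socioeconomic_status")
  for (v in names(direct)) {
    x <- cohort[[direct[[v]]]]
    flags[[v]] <- resolve(v, x, !is.na(x))
  }

  # lack of adherence: OR over direct flag, Morisky-Green, TAI
  mg <- score_morisky(cohort[.morisky_cols])
  tai_bad <- cohort$tai_total < policy$tai_threshold
  sources <- cbind(cohort$nonadherent_any_medication,
                   mg == "non-adherent",
                   tai_bad)
  adh_avail <- rowSums(!is.na(sources)) > 0
  flags$adherence_lack <- resolve("adherence_lack",
                                  rowSums(sources, na.rm = TRUE) > 0,
                                  adh_avail)

  flags$polypharmacy <- resolve("polypharmacy",
                                cohort$chronic_drug_count > 5,
                                !is.na(cohort$chronic_drug_count))

  eq <- as.matrix(cohort[.eq5d_cols])
  eq_avail <- rowSums(is.na(eq)) == 0
  flags$qol_impairment <- resolve(
    "qol_impairment",
    rowSums(eq >= policy$eq5d_severe_level, na.rm = TRUE) > 0,
    eq_avail)

  flags$hospitalisations_ed <- resolve(
    "hospitalisations_ed",
    cohort$admissions_or_ed_visits_12mo >= 2,
    !is.na(cohort$admissions_or_ed_visits_12mo))

  flags$completeness <- rowMeans(derivable)
  flags <- flags[c("patient_id", .flag_ids, "completeness")]
  class(flags) <- c("derived_flags", "data.frame")
  flags
}
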