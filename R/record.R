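# patient record model: column dictionary, validation, CSV round-trip

.boolean_inputs <- c(
  "pregnant_or_postpartum", "cystic_fibrosis",
  "multiple_respiratory_conditions", "other_conditions_under_treatment",
  "mental_disorder_treated", "cognitive_impairment",
  "severe_or_oxygen_therapy", "nonadherent_any_medication",
  "drug_worsening_respiratory", "high_alert_medicine",
  "objectives_not_reached", "complex_hospital_medicine",
  "naive_hospital_medication", "therapy_change_6mo", "smoker",
  "alcohol_or_drug_use", "occupational_particulate_exposure",
  "low_socioeconomic_status"
)

.morisky_cols <- paste0("morisky_", 1:4)
.eq5d_cols <- paste0("eq5d5l_", 1:5)

#' Cohort column dictionary
#'
#' One row per column of the patient-level CSV interchange format. Booleans
#' are written as `0`/`1`, missing values as empty cells,
#' `respiratory_diagnoses` as a `;`-separated list of [disease_catalog()]
#' codes, and Morisky-Green items with `1` = the non-compliant answer
#' (polarity is fixed by the schema to avoid silent inversion).
#'
#' @return A data frame with columns `column`, `type`, `description`.
#' @export
cohort_columns <- function() {
  utils::read.csv(extdata("column_dictionary.csv"), stringsAsFactors = FALSE)
}

.cohort_column_names <- function() {
  c("patient_id", "age_years", "clinic_setting", "pregnant_or_postpartum",
    "cystic_fibrosis", "bmi_kg_m2", "respiratory_diagnoses",
    "multiple_respiratory_conditions", "other_conditions_under_treatment",
    "mental_disorder_treated", "cognitive_impairment",
    "severe_or_oxygen_therapy", "nonadherent_any_medication",
    "drug_worsening_respiratory", "high_alert_medicine",
    "objectives_not_reached", "chronic_drug_count",
    "complex_hospital_medicine", "naive_hospital_medication",
    "therapy_change_6mo", "smoker", "alcohol_or_drug_use",
    "occupational_particulate_exposure", "low_socioeconomic_status",
    "admissions_or_ed_visits_12mo",
    .morisky_cols, "tai_total", .eq5d_cols, "digital_skill")
}

#' Create an empty cohort
#'
#' @param n Number of rows (all fields missing except patient ids
#'   `"p1"`, ..., `"pn"` when `n > 0`).
#' @return A cohort data frame with the full column dictionary.
#' @export
empty_cohort <- function(n = 0L) {
  cols <- .cohort_column_names()
  df <- data.frame(matrix(NA, nrow = n, ncol = length(cols)),
                   stringsAsFactors = FALSE)
  names(df) <- cols
  df$patient_id <- if (n > 0) paste0("p", seq_len(n)) else character(0)
  df$age_years <- as.integer(df$age_years)
  df$clinic_setting <- as.character(df$clinic_setting)
  df$respiratory_diagnoses <- as.character(df$respiratory_diagnoses)
  df$digital_skill <- as.character(df$digital_skill)
  df$bmi_kg_m2 <- as.numeric(df$bmi_kg_m2)
  df$tai_total <- as.integer(df$tai_total)
  for (cc in c("chronic_drug_count", "admissions_or_ed_visits_12mo",
               .eq5d_cols)) {
    df[[cc]] <- as.integer(df[[cc]])
  }
  for (cc in c(.boolean_inputs, .morisky_cols)) df[[cc]] <- as.logical(df[[cc]])
  df
}

.check_range <- function(x, column, lo = NULL, hi = NULL, integer = FALSE) {
  idx <- which(!is.na(x))
  if (integer && any(x[idx] != floor(x[idx]))) {
    stop_input(sprintf("%s out of range: must be an integer (row %d)",
                       column, idx[which(x[idx] != floor(x[idx]))[1]]))
  }
  if (!is.null(lo) && any(x[idx] < lo)) {
    stop_input(sprintf("%s out of range: must be >= %s (row %d)",
                       column, lo, idx[which(x[idx] < lo)[1]]))
  }
  if (!is.null(hi) && any(x[idx] > hi)) {
    stop_input(sprintf("%s out of range: must be <= %s (row %d)",
                       column, hi, idx[which(x[idx] > hi)[1]]))
  }
  invisible(x)
}

#' Validate a cohort data frame
#'
#' Checks the column set against the dictionary (unknown columns are
#' rejected unless `permissive = TRUE`; missing optional columns are added
#' as all-missing), coerces types, and enforces the record invariants:
#' non-negative integer ages, drug counts and admission counts; EQ-5D-5L
#' levels in 1..5 with all five dimensions present when any is; Morisky
#' items all-or-none; TAI totals in 10..50; BMI positive; diagnoses from
#' [disease_catalog()]. Missing optional fields stay missing — nothing is
#' silently defaulted.
#'
#' @param cohort A data frame with at least `patient_id` and `age_years`.
#' @param permissive Keep (and ignore) columns outside the dictionary?
#' @return The validated cohort with canonical column order and types.
#' @export
validate_cohort <- function(cohort, permissive = FALSE) {
  cols <- .cohort_column_names()
  if (!all(c("patient_id", "age_years") %in% names(cohort))) {
    stop_input("cohort must carry at least 'patient_id' and 'age_years'")
  }
  unknown <- setdiff(names(cohort), cols)
  if (length(unknown) && !permissive) {
    stop_input("unknown column(s): ", paste(unknown, collapse = ", "),
               " (use permissive = TRUE to ignore)")
  }
  n <- nrow(cohort)
  out <- empty_cohort(n)
  out$patient_id <- as.character(cohort$patient_id)
  if (any(is.na(out$patient_id) | out$patient_id == "")) {
    stop_input("patient_id missing for row ",
               which(is.na(out$patient_id) | out$patient_id == "")[1])
  }
  if (anyDuplicated(out$patient_id)) {
    stop_input("duplicate patient_id: ",
               out$patient_id[anyDuplicated(out$patient_id)])
  }

  for (cc in intersect(names(cohort), cols)) {
    if (cc %in% c("patient_id")) next
    x <- cohort[[cc]]
    if (cc %in% c(.boolean_inputs, .morisky_cols)) {
      out[[cc]] <- if (is.logical(x)) x else parse_flag(x, cc)
    } else if (cc %in% c("age_years", "chronic_drug_count",
                         "admissions_or_ed_visits_12mo", "tai_total",
                         .eq5d_cols)) {
      out[[cc]] <- if (is.numeric(x)) {
        .check_range(x, cc, integer = TRUE)
        as.integer(x)
      } else parse_int(x, cc)
    } else if (cc == "bmi_kg_m2") {
      out[[cc]] <- if (is.numeric(x)) x else parse_num(x, cc)
    } else {
      x <- as.character(x)
      x[!is.na(x) & trimws(x) == ""] <- NA
      out[[cc]] <- x
    }
  }

  if (any(is.na(out$age_years))) {
    stop_input("age_years out of range: missing (row ",
               which(is.na(out$age_years))[1], ")")
  }
  .check_range(out$age_years, "age_years", lo = 0, integer = TRUE)
  .check_range(out$chronic_drug_count, "chronic_drug_count", lo = 0,
               integer = TRUE)
  .check_range(out$admissions_or_ed_visits_12mo,
               "admissions_or_ed_visits_12mo", lo = 0, integer = TRUE)
  if (any(!is.na(out$bmi_kg_m2) & out$bmi_kg_m2 <= 0)) {
    stop_input("bmi_kg_m2 out of range: must be positive")
  }
  .check_range(out$tai_total, "tai_total", lo = 10, hi = 50, integer = TRUE)

  bad_setting <- !is.na(out$clinic_setting) &
    !out$clinic_setting %in% c("adult", "pediatric")
  if (any(bad_setting)) {
    stop_input("clinic_setting out of range: '",
               out$clinic_setting[which(bad_setting)[1]],
               "' (must be adult or pediatric)")
  }
  bad_skill <- !is.na(out$digital_skill) &
    !out$digital_skill %in% c("advanced", "limited", "none")
  if (any(bad_skill)) {
    stop_input("digital_skill out of range: '",
               out$digital_skill[which(bad_skill)[1]], "'")
  }

  eq <- as.matrix(out[.eq5d_cols])
  partial <- rowSums(is.na(eq)) %in% 1:4
  if (any(partial)) {
    stop_input("eq5d5l_levels: all 5 dimensions required when any is ",
               "present (row ", which(partial)[1], ")")
  }
  for (d in 1:5) {
    x <- out[[.eq5d_cols[d]]]
    bad <- !is.na(x) & (x < 1 | x > 5)
    if (any(bad)) {
      stop_input(sprintf(
        "eq5d5l dimension %d out of range: level %d (row %d; levels are 1..5)",
        d, x[which(bad)[1]], which(bad)[1]))
    }
  }
  mk <- as.matrix(out[.morisky_cols])
  partial <- rowSums(is.na(mk)) %in% 1:3
  if (any(partial)) {
    stop_input("morisky_items: all 4 items required when any is present ",
               "(row ", which(partial)[1], ")")
  }

  dx <- out$respiratory_diagnoses
  for (i in which(!is.na(dx) & dx != "")) {
    codes <- trimws(strsplit(dx[i], ";", fixed = TRUE)[[1]])
    bad <- setdiff(codes, disease_catalog())
    if (length(bad)) {
      stop_input(sprintf(
        "respiratory_diagnoses: unknown code '%s' (row %d)", bad[1], i))
    }
    out$respiratory_diagnoses[i] <- paste(codes, collapse = ";")
  }
  out
}

#' Validate a single raw patient record
#'
#' Convenience wrapper around [validate_cohort()] for one record given as a
#' named list; unnamed/unknown fields raise an error, missing optional
#' fields are marked missing.
#'
#' @param raw Named list with at least `patient_id` and `age_years`.
#' @return A one-row validated cohort data frame.
#' @export
#' @examples
#' validate_record(list(patient_id = "p1", age_years = 70, bmi_kg_m2 = 31))
validate_record <- function(raw) {
  if (!is.list(raw) || is.null(names(raw))) {
    stop_input("raw record must be a named list")
  }
  raw <- lapply(raw, function(x) if (length(x) == 0) NA else x)
  multi <- names(raw)[lengths(raw) > 1]
  for (f in multi) {
    if (f == "morisky_items") {
      if (length(raw[[f]]) != 4) {
        stop_input("morisky_items: all 4 items required when any is present")
      }
      raw[.morisky_cols] <- as.list(as.logical(raw[[f]]))
      raw[[f]] <- NULL
    } else if (f == "eq5d5l_levels") {
      if (length(raw[[f]]) != 5) stop_input("eq5d5l_levels must have 5 entries")
      raw[.eq5d_cols] <- as.list(raw[[f]])
      raw[[f]] <- NULL
    } else if (f == "respiratory_diagnoses") {
      raw[[f]] <- paste(raw[[f]], collapse = ";")
    } else {
      stop_input("field '", f, "' must be scalar")
    }
  }
  validate_cohort(as.data.frame(raw, stringsAsFactors = FALSE))
}

#' Read a cohort CSV
#'
#' Reads the interchange format documented by [cohort_columns()] (UTF-8,
#' comma-delimited, booleans 0/1, missing = empty cell) and validates it.
#'
#' @param path CSV file path.
#' @param permissive Ignore columns outside the dictionary?
#' @return A validated cohort data frame.
#' @export
read_cohort_csv <- function(path, permissive = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(raw, permissive = permissive)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]; writing then re-reading is byte-stable.
#'
#' @param cohort A validated cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (cc in c(.boolean_inputs, .morisky_cols)) out[[cc]] <- fmt_flag(out[[cc]])
  for (cc in setdiff(names(out), c(.boolean_inputs, .morisky_cols))) {
    out[[cc]] <- fmt_val(out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
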