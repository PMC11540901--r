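# routing, additive scoring, overrides

#' Route patients between the adult stratification model and the pediatric
#' pathway
#'
#' Children aged 0-15, and under-18s followed in a pediatric clinic, are
#' excluded from the adult tool (they have a dedicated pediatric chronic
#' patient model). Under-18s seen in an adult clinic stay on the adult path
#' but are automatically prioritised to level 1. A missing `clinic_setting`
#' is treated as adult.
#'
#' @param cohort A validated cohort data frame.
#' @return A data frame with `patient_id`, `routing`
#'   (`"adult_scored"`/`"pediatric_model_excluded"`) and
#'   `pediatric_in_adult_clinic` (logical override marker).
#' @export
#' @examples
#' route_patient(validate_record(list(patient_id = "a", age_years = 12,
#'                                    clinic_setting = "pediatric")))
route_patient <- function(cohort) {
  cohort <- validate_cohort(cohort)
  setting <- ifelse(is.na(cohort$clinic_setting), "adult",
                    cohort$clinic_setting)
  excluded <- cohort$age_years <= 15 |
    (cohort$age_years < 18 & setting == "pediatric")
  override <- !excluded & cohort$age_years < 18 & setting == "adult"
  data.frame(patient_id = cohort$patient_id,
             routing = ifelse(excluded, "pediatric_model_excluded",
                              "adult_scored"),
             pediatric_in_adult_clinic = override,
             stringsAsFactors = FALSE)
}

#' Score derived flags against a weight table
#'
#' The additive engine: each triggered entry contributes its points; within
#' an exclusion set only the highest-weight triggered entry counts (so a
#' cystic fibrosis patient with BMI 17 scores 3, not 3 + 1). The total is
#' the exact integer sum of the per-variable contributions.
#'
#' @param flags A `derived_flags` data frame (see [derive_flags()]), or any
#'   data frame with one logical column per trigger id in `wt`.
#' @param wt A [default_weight_table()]-style `weight_table`.
#' @return A data frame with `patient_id` (if present in `flags`), one
#'   contribution column per variable id, and `total_score`.
#' @export
score_flags <- function(flags, wt = default_weight_table()) {
  wt <- validate_weight_table(wt)
  missing_triggers <- setdiff(wt$trigger, names(flags))
  if (length(missing_triggers)) {
    stop_input("flags lack trigger column(s): ",
               paste(missing_triggers, collapse = ", "))
  }
  n <- nrow(flags)
  # points awarded per weight entry (n x entries)
  awarded <- matrix(0L, n, nrow(wt))
  for (i in seq_len(nrow(wt))) {
    trig <- flags[[wt$trigger[i]]]
    awarded[!is.na(trig) & trig, i] <- wt$points[i]
  }
  # cap exclusion sets: keep only the highest awarded entry per set
  for (s in unique(stats::na.omit(wt$exclusion_set))) {
    idx <- which(!is.na(wt$exclusion_set) & wt$exclusion_set == s)
    if (length(idx) < 2) next
    sub <- awarded[, idx, drop = FALSE]
    keep <- max.col(sub, ties.method = "first")
    capped <- matrix(0L, n, length(idx))
    capped[cbind(seq_len(n), keep)] <- sub[cbind(seq_len(n), keep)]
    awarded[, idx] <- capped
  }
  vars <- unique(wt$variable_id)
  contrib <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    contrib[, v] <- as.integer(
      rowSums(awarded[, wt$variable_id == v, drop = FALSE]))
  }
  out <- as.data.frame(contrib)
  if (!is.null(flags$patient_id)) {
    out <- cbind(patient_id = flags$patient_id, out,
                 stringsAsFactors = FALSE)
  }
  out$total_score <- as.integer(rowSums(contrib))
  out
}

#' Score a cohort end to end
#'
#' Validates, routes, derives flags and scores a raw cohort. Pediatric-
#' excluded records keep a row (for the accounting) with `NA` score.
#' Overrides are classification directives, not score modifiers: a pregnant
#' or pediatric-in-adult-clinic patient keeps their arithmetic total and is
#' lifted to level 1 at classification time. When both overrides apply, the
#' routing-stage `pediatric_in_adult_clinic` takes precedence.
#'
#' @param cohort Raw or validated cohort data frame, or a CSV path.
#' @param wt Weight table.
#' @param policy A [derivation_policy()].
#' @return A `score_result` data frame: `patient_id`, `routing`, one
#'   contribution column per variable, `total_score`, `override`
#'   (`none`/`pregnancy`/`pediatric_in_adult_clinic`), `completeness`.
#' @export
score_cohort <- function(cohort, wt = default_weight_table(),
                         policy = derivation_policy()) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  cohort <- validate_cohort(cohort)
  routing <- route_patient(cohort)
  flags <- derive_flags(cohort, policy)
  scored <- score_flags(flags, wt)

  override <- rep("none", nrow(cohort))
  ov_rows <- wt[!is.na(wt$override) & wt$override == "level1", , drop = FALSE]
  for (i in seq_len(nrow(ov_rows))) {
    trig <- flags[[ov_rows$trigger[i]]]
    override[!is.na(trig) & trig] <- ov_rows$variable_id[i]
  }
  override[routing$pediatric_in_adult_clinic] <- "pediatric_in_adult_clinic"

  out <- cbind(
    data.frame(patient_id = cohort$patient_id, routing = routing$routing,
               stringsAsFactors = FALSE),
    scored[setdiff(names(scored), "patient_id")]
  )
  out$override <- override
  out$completeness <- flags$completeness
  excluded <- out$routing == "pediatric_model_excluded"
  var_cols <- c(unique(wt$variable_id), "total_score")
  out[excluded, var_cols] <- NA_integer_
  out$override[excluded] <- "none"
  class(out) <- c("score_result", "data.frame")
  out
}

#' Write score results to CSV
#'
#' One row per patient, one column per variable contribution plus total,
#' override and routing; byte-stable under read/write.
#'
#' @param scores A `score_result` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  out <- scores
  for (cc in names(out)) out[[cc]] <- fmt_val(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
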