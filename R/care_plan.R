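# cumulative intervention plans, monitoring frequency, telemedicine triage

#' Default pharmaceutical-care intervention catalog
#'
#' Twenty interventions across three categories: pharmacotherapeutic
#' monitoring (7), patient training and education (7) and care coordination
#' (6). Interventions are cumulative across priority levels: an entry's
#' `level` is the least-intensive priority at which it activates, so a
#' level-1 patient receives the full catalog. The category names and sizes
#' are fixed by the published model; the individual labels and their level
#' assignments are editable defaults (the source figure itemizing them is
#' not reproducible as text) — treat them as a template, not as verified
#' clinical content.
#'
#' @return An `intervention_catalog` data frame with columns
#'   `intervention_id`, `label`, `category`, `level`.
#' @export
default_intervention_catalog <- function() {
  load_intervention_catalog(extdata("interventions.yaml"))
}

#' Validate an intervention catalog
#'
#' @param catalog Data frame with `intervention_id`, `label`, `category`
#'   in `pharmacotherapeutic_monitoring` / `training_education` /
#'   `care_coordination`, and `level` in 1..3.
#' @return The catalog with class `intervention_catalog`.
#' @export
validate_intervention_catalog <- function(catalog) {
  need <- c("intervention_id", "label", "category", "level")
  if (!all(need %in% names(catalog))) {
    stop_input("catalog must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(catalog$intervention_id)) {
    stop_input("duplicate intervention_id: ",
               catalog$intervention_id[anyDuplicated(catalog$intervention_id)])
  }
  ok_cat <- c("pharmacotherapeutic_monitoring", "training_education",
              "care_coordination")
  bad <- setdiff(unique(catalog$category), ok_cat)
  if (length(bad)) stop_input("unknown intervention category: ", bad[1])
  if (any(!catalog$level %in% 1:3)) {
    stop_input("intervention level must be 1, 2 or 3")
  }
  catalog$level <- as.integer(catalog$level)
  if (!inherits(catalog, "intervention_catalog")) {
    class(catalog) <- c("intervention_catalog", "data.frame")
  }
  catalog
}

#' Load an intervention catalog from YAML
#' @param path YAML file with an `interventions` list.
#' @return A validated `intervention_catalog`.
#' @export
load_intervention_catalog <- function(path) {
  cfg <- yaml::read_yaml(path)
  rows <- lapply(cfg$interventions, function(x) {
    data.frame(intervention_id = x$intervention_id, label = x$label,
               category = x$category, level = x$level,
               stringsAsFactors = FALSE)
  })
  validate_intervention_catalog(do.call(rbind, rows))
}

#' Write an intervention catalog to YAML
#' @param catalog A validated catalog.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervention_catalog <- function(catalog, path) {
  catalog <- validate_intervention_catalog(catalog)
  entries <- lapply(seq_len(nrow(catalog)), function(i) {
    list(intervention_id = catalog$intervention_id[i],
         label = catalog$label[i], category = catalog$category[i],
         level = catalog$level[i])
  })
  yaml::write_yaml(list(interventions = entries), path)
  invisible(path)
}

#' Default monitoring-frequency map
#'
#' Follow-up frequency by priority level. The published model fixes that
#' frequency scales with priority but does not print the values; the
#' shipped defaults (level 1 monthly, 2 quarterly, 3 semi-annual) are
#' placeholders meant to be replaced by local policy.
#'
#' @return Named character vector, names `"1"`, `"2"`, `"3"`.
#' @export
default_frequency_map <- function() {
  unlist(yaml::read_yaml(extdata("frequencies.yaml")))
}

#' Build the care plan for a priority level
#'
#' Active interventions are all catalog entries whose activation level is
#' numerically greater than or equal to the patient's level (level 1, the
#' most complex tier, activates everything), which makes plans cumulative:
#' `plan(1)` contains `plan(2)` contains `plan(3)`.
#'
#' @param level Priority level, 1, 2 or 3.
#' @param catalog An `intervention_catalog`.
#' @param frequencies Frequency map, names `"1"`..`"3"`.
#' @return A list of class `care_plan`: `level`, `interventions` (the
#'   active catalog rows), `monitoring_frequency`.
#' @export
#' @examples
#' nrow(build_plan(1)$interventions)  # full default catalog: 20
build_plan <- function(level, catalog = default_intervention_catalog(),
                       frequencies = default_frequency_map()) {
  if (!is_scalar_int(level) || !level %in% 1:3) {
    stop_input("level must be 1, 2 or 3")
  }
  catalog <- validate_intervention_catalog(catalog)
  if (!as.character(level) %in% names(frequencies)) {
    stop_input("frequency map is missing level ", level)
  }
  structure(list(
    level = as.integer(level),
    interventions = catalog[catalog$level >= level, , drop = FALSE],
    monitoring_frequency = unname(frequencies[[as.character(level)]])
  ), class = "care_plan")
}

#' Triage patients into telemedicine groups
#'
#' Group A: advanced digital skills, full telemedicine toolset. Group B:
#' limited digital proficiency but able to adapt. Patients with no digital
#' capability — or with the skill field missing — are not eligible (a
#' missing input is flagged in the `note` attribute).
#'
#' @param digital_skill Character vector with values `advanced`, `limited`,
#'   `none` or `NA`.
#' @return Character vector in `A`/`B`/`not_eligible`, with a `note`
#'   attribute marking `"missing input"` positions.
#' @export
#' @examples
#' triage_telemedicine(c("advanced", "limited", "none", NA))
triage_telemedicine <- function(digital_skill) {
  bad <- !is.na(digital_skill) &
    !digital_skill %in% c("advanced", "limited", "none")
  if (any(bad)) {
    stop_input("unknown digital_skill: '", digital_skill[which(bad)[1]], "'")
  }
  out <- rep("not_eligible", length(digital_skill))
  out[!is.na(digital_skill) & digital_skill == "advanced"] <- "A"
  out[!is.na(digital_skill) & digital_skill == "limited"] <- "B"
  note <- rep(NA_character_, length(digital_skill))
  note[is.na(digital_skill)] <- "missing input"
  attr(out, "note") <- note
  out
}

.recommendations_cache <- new.env(parent = emptyenv())

#' Per-disease teleconsultation recommendations
#'
#' Static lookup of pharmaceutical-care recommendations for telematic
#' interviews, by disease. The recommendation table covers some diseases
#' outside the stratification model's catalog (tuberculosis, pulmonary
#' embolism, silicosis) and not all model diseases; an uncovered code
#' returns an empty list with a message.
#'
#' @param disease A single disease code.
#' @param table Optional recommendation table (named list of character
#'   vectors); defaults to the shipped one.
#' @return Character vector of recommendations (possibly empty).
#' @export
#' @examples
#' lookup_recommendations("asthma")
lookup_recommendations <- function(disease, table = NULL) {
  if (is.null(table)) {
    if (is.null(.recommendations_cache$table)) {
      .recommendations_cache$table <- lapply(
        yaml::read_yaml(extdata("teleconsultation_recommendations.yaml")),
        as.character)
    }
    table <- .recommendations_cache$table
  }
  stopifnot(length(disease) == 1)
  if (!disease %in% names(table)) {
    message("no teleconsultation recommendations for '", disease, "'")
    return(character(0))
  }
  table[[disease]]
}

#' Telepharmacy digital-tool selection checklist
#'
#' The criteria a digital tool should meet before adoption for telepharmacy
#' (integration, maintenance, training, proactive risk assessment, update
#' policy, user experience, support service). Shipped as a reference
#' checklist; the package does not evaluate tools against it.
#'
#' @return Data frame with columns `area`, `description`.
#' @export
telepharmacy_tool_checklist <- function() {
  cfg <- yaml::read_yaml(extdata("telepharmacy_tool_checklist.yaml"))
  data.frame(area = vapply(cfg, `[[`, "", "area"),
             description = vapply(cfg, `[[`, "", "description"),
             stringsAsFactors = FALSE)
}

#' Build per-patient care plans
#'
#' Joins classified scores with the catalog, frequency map and telemedicine
#' triage. Pediatric-excluded records get an empty plan row.
#'
#' @param classified Output of [classify()] on a [score_cohort()] result.
#' @param cohort The validated cohort (source of `digital_skill`).
#' @param catalog An `intervention_catalog`.
#' @param frequencies Frequency map.
#' @return Data frame: `patient_id`, `priority_level`, `interventions`
#'   (`;`-separated ids), `n_interventions`, `monitoring_frequency`,
#'   `telemedicine_group`, `telemedicine_note`.
#' @export
build_plans <- function(classified, cohort,
                        catalog = default_intervention_catalog(),
                        frequencies = default_frequency_map()) {
  cohort <- validate_cohort(cohort)
  catalog <- validate_intervention_catalog(catalog)
  idx <- match(classified$patient_id, cohort$patient_id)
  if (anyNA(idx)) stop_input("classified ids missing from cohort")
  skill <- cohort$digital_skill[idx]
  tele <- triage_telemedicine(skill)
  plans <- lapply(1:3, build_plan, catalog = catalog,
                  frequencies = frequencies)
  lv <- classified$priority_level
  iv_by_level <- vapply(plans, function(p) {
    paste(p$interventions$intervention_id, collapse = ";")
  }, character(1))
  ivs <- ifelse(is.na(lv), "", iv_by_level[lv])
  data.frame(
    patient_id = classified$patient_id,
    priority_level = lv,
    interventions = ivs,
    n_interventions = ifelse(ivs == "", 0L,
                             lengths(strsplit(ivs, ";", fixed = TRUE))),
    monitoring_frequency = ifelse(
      is.na(lv), NA_character_,
      unname(frequencies[as.character(ifelse(is.na(lv), 1L, lv))])),
    telemedicine_group = ifelse(is.na(lv), "not_eligible", tele),
    telemedicine_note = ifelse(is.na(lv), "pediatric_model_excluded",
                               attr(tele, "note")),
    stringsAsFactors = FALSE
  )
}
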