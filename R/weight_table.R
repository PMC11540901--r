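# the variable weight table: defaults, config IO, validation

.default_weight_rows <- function() {
  e <- function(variable_id, group, trigger, points,
                exclusion_set = NA_character_, override = NA_character_) {
    data.frame(variable_id = variable_id, group = group, trigger = trigger,
               points = as.integer(points), exclusion_set = exclusion_set,
               override = override, stringsAsFactors = FALSE)
  }
  rbind(
    e("pregnancy", "demographic", "pregnancy", 0, override = "level1"),
    e("age", "demographic", "age_65_plus", 2),
    e("bmi", "demographic", "obesity", 3, exclusion_set = "bmi"),
    e("bmi", "demographic", "malnutrition", 1, exclusion_set = "bmi"),
    e("bmi", "demographic", "cf_malnutrition", 3, exclusion_set = "bmi"),
    e("respiratory_comorbidity", "clinical", "respiratory_comorbidity", 2),
    e("non_respiratory_comorbidity", "clinical",
      "non_respiratory_comorbidity", 3),
    e("mental_disorders", "clinical", "mental_disorders", 3),
    e("cognitive_impairment", "clinical", "cognitive_impairment", 4),
    e("severity", "clinical", "severity", 2),
    e("adherence_lack", "treatment", "adherence_lack", 4),
    e("worsening_drugs", "treatment", "worsening_drugs", 4),
    e("high_alert_medicines", "treatment", "high_alert_medicines", 4),
    e("objectives_not_reached", "treatment", "objectives_not_reached", 2),
    e("polypharmacy", "treatment", "polypharmacy", 3),
    e("complex_medicines", "treatment", "complex_medicines", 1),
    e("naive_patient", "treatment", "naive_patient", 1),
    e("therapy_changes", "treatment", "therapy_changes", 1),
    e("tobacco", "socio_sanitary", "tobacco", 4),
    e("alcohol_drugs", "socio_sanitary", "alcohol_drugs", 3),
    e("occupational_exposure", "socio_sanitary", "occupational_exposure", 3),
    e("low_ses", "socio_sanitary", "low_ses", 3),
    e("qol_impairment", "socio_sanitary", "qol_impairment", 3),
    e("hospitalisations_ed", "healthcare_use", "hospitalisations_ed", 3)
  )
}

#' Default stratification weight table
#'
#' The final consensus weights of the 22-variable tool. Entries are one row
#' per scored condition: the `bmi` variable has three rows (obesity 3,
#' malnutrition 1, CF-malnutrition 3) sharing the `bmi` exclusion set, so a
#' record contributes at most one of them; `pregnancy` carries 0 points but
#' an automatic level-1 override; under-18 routing is handled by
#' [route_patient()], not by table rows.
#'
#' @return A `weight_table` data frame with columns `variable_id`, `group`,
#'   `trigger`, `points`, `exclusion_set`, `override`, and a `version`
#'   attribute.
#' @export
#' @examples
#' wt <- default_weight_table()
#' group_max_scores(wt)
default_weight_table <- function() {
  wt <- .default_weight_rows()
  attr(wt, "version") <- "final"
  class(wt) <- c("weight_table", "data.frame")
  validate_weight_table(wt)
}

#' Validate a weight table
#'
#' Enforces the structural invariants: 22 distinct variable ids in groups
#' of 3/5/8/5/1, non-negative integer points, no duplicated
#' (variable, trigger) pair, and exclusion sets spanning a single group.
#'
#' @param wt A weight-table data frame.
#' @return `wt`, with class `weight_table`.
#' @export
validate_weight_table <- function(wt) {
  need <- c("variable_id", "group", "trigger", "points")
  if (!all(need %in% names(wt))) {
    stop_input("weight table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(wt$exclusion_set)) wt$exclusion_set <- NA_character_
  if (is.null(wt$override)) wt$override <- NA_character_
  if (any(is.na(wt$points)) || any(wt$points < 0) ||
      any(wt$points != floor(wt$points))) {
    stop_input("weight table points must be non-negative integers")
  }
  wt$points <- as.integer(wt$points)
  dup <- duplicated(wt[c("variable_id", "trigger")])
  if (any(dup)) {
    stop_input("duplicate weight entry: ", wt$variable_id[dup][1], "/",
               wt$trigger[dup][1])
  }
  bad_group <- setdiff(unique(wt$group), names(.variables))
  if (length(bad_group)) stop_input("unknown variable group: ", bad_group[1])
  vars <- unique(wt[c("variable_id", "group")])
  if (anyDuplicated(vars$variable_id)) {
    stop_input("variable assigned to more than one group: ",
               vars$variable_id[anyDuplicated(vars$variable_id)])
  }
  sizes <- c(demographic = 3L, clinical = 5L, treatment = 8L,
             socio_sanitary = 5L, healthcare_use = 1L)
  got <- table(factor(vars$group, levels = names(sizes)))
  for (g in names(sizes)) {
    if (got[[g]] != sizes[[g]]) {
      stop_input(sprintf("group %s has %d of %d variables", g, got[[g]],
                         sizes[[g]]))
    }
  }
  for (s in unique(stats::na.omit(wt$exclusion_set))) {
    if (length(unique(wt$group[!is.na(wt$exclusion_set) &
                               wt$exclusion_set == s])) > 1) {
      stop_input("exclusion set '", s, "' spans multiple groups")
    }
  }
  bad_ov <- !is.na(wt$override) & wt$override != "level1"
  if (any(bad_ov)) stop_input("unknown override: ", wt$override[bad_ov][1])
  if (!inherits(wt, "weight_table")) class(wt) <- c("weight_table",
                                                    "data.frame")
  if (is.null(attr(wt, "version"))) attr(wt, "version") <- "custom"
  wt
}

#' Load a weight table from a YAML config
#'
#' @param path YAML file with a `version` label and an `entries` list of
#'   `{variable_id, group, trigger, points, exclusion_set?, override?}`
#'   maps (see the shipped `weights.yaml`).
#' @return A validated `weight_table`.
#' @export
load_weight_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entries)) stop_input("weight config has no 'entries'")
  rows <- lapply(cfg$entries, function(x) {
    data.frame(variable_id = x$variable_id %||% NA_character_,
               group = x$group %||% NA_character_,
               trigger = x$trigger %||% NA_character_,
               points = x$points %||% NA_integer_,
               exclusion_set = x$exclusion_set %||% NA_character_,
               override = x$override %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  wt <- do.call(rbind, rows)
  attr(wt, "version") <- cfg$version %||% "custom"
  validate_weight_table(wt)
}

#' Write a weight table to a YAML config
#'
#' Canonical serialization; `load_weight_table(write_weight_table(wt, f))`
#' round-trips unchanged.
#'
#' @param wt A validated `weight_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(wt, path) {
  wt <- validate_weight_table(wt)
  entries <- lapply(seq_len(nrow(wt)), function(i) {
    x <- list(variable_id = wt$variable_id[i], group = wt$group[i],
              trigger = wt$trigger[i], points = wt$points[i])
    if (!is.na(wt$exclusion_set[i])) x$exclusion_set <- wt$exclusion_set[i]
    if (!is.na(wt$override[i])) x$override <- wt$override[i]
    x
  })
  yaml::write_yaml(list(version = attr(wt, "version"), entries = entries),
                   path)
  invisible(path)
}

#' Maximum attainable score per variable group
#'
#' Sums, within each group, the maximum points a single record can collect:
#' entries in an exclusion set contribute only the set's largest weight.
#' With the default table: demographic 5, clinical 14, treatment 20,
#' socio-sanitary 16, healthcare use 3 (total 58).
#'
#' @param wt A `weight_table`.
#' @return Named integer vector, one entry per group plus `"total"`.
#' @export
group_max_scores <- function(wt = default_weight_table()) {
  wt <- validate_weight_table(wt)
  key <- ifelse(is.na(wt$exclusion_set),
                paste0("var:", wt$variable_id, ":", wt$trigger),
                paste0("set:", wt$exclusion_set))
  per_unit <- tapply(wt$points, key, max)
  unit_group <- tapply(wt$group, key, function(g) g[1])
  out <- tapply(as.integer(per_unit), unit_group[names(per_unit)], sum)
  out <- out[names(.variables)]
  c(out, total = sum(out))
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Stratification weight table (version:", attr(x, "version"), ")\n")
  cat(length(unique(x$variable_id)), "variables,", nrow(x), "entries;",
      "max score", group_max_scores(x)[["total"]], "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
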