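#' Respiratory disease catalog
#'
#' The eight respiratory diseases covered by the stratification model:
#' severe asthma, cystic fibrosis, COPD (including alpha-1 antitrypsin
#' deficiency, bronchitis and emphysema), chronic rhinosinusitis with nasal
#' polyposis, idiopathic pulmonary fibrosis, other interstitial lung
#' diseases (hypersensitivity pneumonitis, silicosis), non-CF
#' bronchiectasis, and pulmonary hypertension.
#'
#' @return Character vector of disease codes accepted in
#'   `respiratory_diagnoses`.
#' @export
#' @examples
#' disease_catalog()
disease_catalog <- function() {
  c("asthma", "cystic_fibrosis", "copd", "nasal_polyposis",
    "ipf", "ild_other", "bronchiectasis", "pulmonary_hypertension")
}

# variable ids of the 22 stratification variables, by group
.variables <- list(
  demographic    = c("pregnancy", "age", "bmi"),
  clinical       = c("respiratory_comorbidity", "non_respiratory_comorbidity",
                     "mental_disorders", "cognitive_impairment", "severity"),
  treatment      = c("adherence_lack", "worsening_drugs",
                     "high_alert_medicines", "objectives_not_reached",
                     "polypharmacy", "complex_medicines", "naive_patient",
                     "therapy_changes"),
  socio_sanitary = c("tobacco", "alcohol_drugs", "occupational_exposure",
                     "low_ses", "qol_impairment"),
  healthcare_use = c("hospitalisations_ed")
)

# trigger/flag ids: one per scored condition; the bmi variable has three
# mutually exclusive categories, pregnancy and age have one flag each
.flag_ids <- c("pregnancy", "age_65_plus",
               "obesity", "malnutrition", "cf_malnutrition",
               .variables$clinical, .variables$treatment,
               .variables$socio_sanitary, .variables$healthcare_use)

#' Stratification variable catalog
#'
#' The 22 consensus variables of the stratification tool, partitioned into
#' five groups: demographic (3), clinical (5), treatment-related (8),
#' socio-sanitary (5) and healthcare-resource use (1).
#'
#' @return A data frame with columns `variable_id` and `group`.
#' @export
#' @examples
#' table(variable_catalog()$group)
variable_catalog <- function() {
  data.frame(
    variable_id = unlist(.variables, use.names = FALSE),
    group = rep(names(.variables), lengths(.variables)),
    stringsAsFactors = FALSE
  )
}
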