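version: final
entries:
- variable_id: pregnancy
  group: demographic
  trigger: pregnancy
  points: 0
  override: level1
- variable_id: age
  group: demographic
  trigger: age_65_plus
  points: 2
- variable_id: bmi
  group: demographic
  trigger: obesity
  points: 3
  exclusion_set: bmi
- variable_id: bmi
  group: demographic
  trigger: malnutrition
  points: 1
  exclusion_set: bmi
- variable_id: bmi
  group: demographic
  trigger: cf_malnutrition
  points: 3
  exclusion_set: bmi
- variable_id: respiratory_comorbidity
  group: clinical
  trigger: respiratory_comorbidity
  points: 2
- variable_id: non_respiratory_comorbidity
  group: clinical
  trigger: non_respiratory_comorbidity
  points: 3
- variable_id: mental_disorders
  group: clinical
  trigger: mental_disorders
  points: 3
- variable_id: cognitive_impairment
  group: clinical
  trigger: cognitive_impairment
  points: 4
- variable_id: severity
  group: clinical
  trigger: severity
  points: 2
- variable_id: adherence_lack
  group: treatment
  trigger: adherence_lack
  points: 4
- variable_id: worsening_drugs
  group: treatment
  trigger: worsening_drugs
  points: 4
- variable_id: high_alert_medicines
  group: treatment
  trigger: high_alert_medicines
  points: 4
- variable_id: objectives_not_reached
  group: treatment
  trigger: objectives_not_reached
  points: 2
- variable_id: polypharmacy
  group: treatment
  trigger: polypharmacy
  points: 3
- variable_id: complex_medicines
  group: treatment
  trigger: complex_medicines
  points: 1
- variable_id: naive_patient
  group: treatment
  trigger: naive_patient
  points: 1
- variable_id: therapy_changes
  group: treatment
  trigger: therapy_changes
  points: 1
- variable_id: tobacco
  group: socio_sanitary
  trigger: tobacco
  points: 4
- variable_id: alcohol_drugs
  group: socio_sanitary
  trigger: alcohol_drugs
  points: 3
- variable_id: occupational_exposure
  group: socio_sanitary
  trigger: occupational_exposure
  points: 3
- variable_id: low_ses
  group: socio_sanitary
  trigger: low_ses
  points: 3
- variable_id: qol_impairment
  group: socio_sanitary
  trigger: qol_impairment
  points: 3
- variable_id: hospitalisations_ed
  group: healthcare_use
  trigger: hospitalisations_ed
  points: 3
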