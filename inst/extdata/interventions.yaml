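interventions:
- intervention_id: pm_appropriateness
  label: Review appropriateness of the prescribed treatment plan
  category: pharmacotherapeutic_monitoring
  level: 3
- intervention_id: pm_effectiveness
  label: Review treatment effectiveness against therapeutic objectives
  category: pharmacotherapeutic_monitoring
  level: 3
- intervention_id: pm_safety
  label: Review treatment safety, adverse effects and interactions
  category: pharmacotherapeutic_monitoring
  level: 3
- intervention_id: pm_adherence_check
  label: Structured adherence assessment (Morisky-Green, TAI)
  category: pharmacotherapeutic_monitoring
  level: 2
- intervention_id: pm_high_alert_review
  label: Focused review of high-alert and respiratory-worsening medicines
  category: pharmacotherapeutic_monitoring
  level: 2
- intervention_id: pm_intensive_followup
  label: Intensified pharmacotherapeutic follow-up between visits
  category: pharmacotherapeutic_monitoring
  level: 1
- intervention_id: pm_individual_plan
  label: Individualized pharmacotherapeutic optimization plan
  category: pharmacotherapeutic_monitoring
  level: 1
- intervention_id: te_medication_info
  label: Information on medication, dosing and storage
  category: training_education
  level: 3
- intervention_id: te_device_technique
  label: Inhaler and administration-device technique training
  category: training_education
  level: 3
- intervention_id: te_admin_support
  label: Support with administrative processing of hospital treatments
  category: training_education
  level: 3
- intervention_id: te_coresponsibility
  label: Promotion of co-responsibility in treatment outcomes
  category: training_education
  level: 2
- intervention_id: te_lifestyle
  label: Education on lifestyle measures and vaccination
  category: training_education
  level: 2
- intervention_id: te_caregiver_training
  label: Caregiver training for complex administration
  category: training_education
  level: 1
- intervention_id: te_reinforced_education
  label: Reinforced individual education sessions
  category: training_education
  level: 1
- intervention_id: cc_ehr_documentation
  label: Documentation of interventions in the electronic health record
  category: care_coordination
  level: 3
- intervention_id: cc_protocols
  label: Application of shared protocols, guidelines and SOPs
  category: care_coordination
  level: 3
- intervention_id: cc_pulmonology_liaison
  label: Coordination with the pulmonology team
  category: care_coordination
  level: 2
- intervention_id: cc_primary_care_liaison
  label: Coordination with primary care on treatment changes
  category: care_coordination
  level: 2
- intervention_id: cc_social_services
  label: Referral and coordination with social services
  category: care_coordination
  level: 1
- intervention_id: cc_multidisciplinary_review
  label: Multidisciplinary case review across care levels
  category: care_coordination
  level: 1
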