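# per-disease pharmaceutical-care recommendations for teleconsultation;
# this catalog intentionally covers some diseases outside the
# stratification model (tuberculosis, pulmonary embolism, silicosis)
asthma:
- 'Checking adherence to inhalers: TAI'
- 'Reinforcing inhaler technique: SEPAR ForoAsma; GEMA Inhalapp, Inhalers
  and Inhalcheck (requires registration by the pharmacist)'
bronchiectasis:
- 'Review the aerosol therapy technique using one of the following
  platforms: SEPAR ForoAsma, GEMA Inhalapp, Inhalers and Inhalcheck
  (requires registration by the pharmacist)'
- Vaccination reminder (flu and pneumococcal)
copd:
- Review of smoking habits
- Reinforce physical exercise (30 min/day)
- Check compliance with non-pharmacological treatment (oxygen therapy,
  vaccination)
- Carry out the TAI questionnaire
- 'Reinforce inhalation technique: SEPAR ForoAsma; GEMA Inhalapp, Inhalers
  and Inhalcheck (requires registration by the pharmacist)'
ipf:
- 'Offer non-pharmacological measures: diet, sun protection and probiotics'
- Vaccination reminders (flu and pneumococcal)
- Thoroughly review side effects
cystic_fibrosis:
- Remind patients to monitor their pulse, weight and height
- Encourage proper adherence to treatment
- Check for proper inhalation technique and correct hygiene of the
  material used
- 'Encourage non-pharmacological measures: use of masks, hand washing,
  avoidance of enclosed areas and proper nutrition'
pulmonary_hypertension:
- Reminder of the need for contraceptive use in fertile women
- Reinforce adherence to concomitant treatment
pulmonary_embolism:
- Ensure correct administration of anticoagulants, as well as INR
  monitoring
- Encourage smoking cessation
silicosis:
- Assess the degree of motivation to quit smoking
- 'Offer advice on how to control withdrawal symptoms: irritability,
  increase in appetite, insomnia'
tuberculosis:
- 'Monitor toxicity: fever, visual, digestive or skin disorders'
- Review the administration schedule
- Reinforce adherence to treatment
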