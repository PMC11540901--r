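flag,p1,p2,p3
age_65_plus,12,36,42
malnutrition,2,1,1
obesity,10,16,18
respiratory_comorbidity,9,30,34
non_respiratory_comorbidity,20,59,62
mental_disorders,6,8,8
cognitive_impairment,4,7,3
severity,19,48,40
adherence_lack,16,28,27
worsening_drugs,9,7,5
high_alert_medicines,18,45,28
objectives_not_reached,15,26,25
polypharmacy,19,63,65
complex_medicines,17,47,71
naive_patient,14,23,32
therapy_changes,15,34,54
tobacco,7,6,7
alcohol_drugs,1,2,1
occupational_exposure,5,5,4
low_ses,3,3,1
qol_impairment,16,49,32
hospitalisations_ed,16,30,24
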