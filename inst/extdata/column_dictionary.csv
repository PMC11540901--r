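column,type,description
patient_id,string,Opaque unique patient identifier
age_years,integer,Age in completed years (>= 0); required
clinic_setting,enum,adult or pediatric; empty treated as adult for routing
pregnant_or_postpartum,boolean,Pregnant or within the postpartum window (convention: 12 months)
cystic_fibrosis,boolean,Cystic fibrosis diagnosis (drives the CF-specific BMI weight)
bmi_kg_m2,number,Body mass index in kg/m2; positive
respiratory_diagnoses,list,Semicolon-separated disease codes from disease_catalog()
multiple_respiratory_conditions,boolean,Multiple respiratory conditions under treatment
other_conditions_under_treatment,boolean,Non-respiratory conditions under treatment
mental_disorder_treated,boolean,Mental or behavioral disorder under treatment
cognitive_impairment,boolean,Mild to severe cognitive-sensory impairment
severe_or_oxygen_therapy,boolean,Severe pathology or oxygen therapy requirement (input flag)
nonadherent_any_medication,boolean,Known non-adherence to any prescribed medication
drug_worsening_respiratory,boolean,On drugs that can worsen the respiratory pathology
high_alert_medicine,boolean,Prescribed a medicine on the ISMP high-alert list (input flag)
objectives_not_reached,boolean,Pharmacotherapy objectives not reached
chronic_drug_count,integer,Number of chronic drugs in regular use (>= 0)
complex_hospital_medicine,boolean,Hospital medication requiring pre-administration handling or a device
naive_hospital_medication,boolean,Naive to hospital medication
therapy_change_6mo,boolean,Drug-therapy change in the last 6 months
smoker,boolean,Current smoker
alcohol_or_drug_use,boolean,Alcoholism and/or drug addiction
occupational_particulate_exposure,boolean,Occupational exposure to particulate matter
low_socioeconomic_status,boolean,Unfavourable socio-economic conditions
admissions_or_ed_visits_12mo,integer,Admissions and/or emergency visits for respiratory decompensation in 12 months (>= 0)
morisky_1,boolean,Morisky-Green item 1; 1 = non-compliant answer
morisky_2,boolean,Morisky-Green item 2; 1 = non-compliant answer
morisky_3,boolean,Morisky-Green item 3; 1 = non-compliant answer
morisky_4,boolean,Morisky-Green item 4; 1 = non-compliant answer
tai_total,integer,Test of Adherence to Inhalers total (10..50; >= 50 = good adherence)
eq5d5l_1,integer,EQ-5D-5L mobility level (1..5)
eq5d5l_2,integer,EQ-5D-5L self-care level (1..5)
eq5d5l_3,integer,EQ-5D-5L usual-activities level (1..5)
eq5d5l_4,integer,EQ-5D-5L pain/discomfort level (1..5)
eq5d5l_5,integer,EQ-5D-5L anxiety/depression level (1..5)
digital_skill,enum,"advanced, limited or none; drives telemedicine triage"
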