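column,type,mandatory,description
center_id,character,TRUE,Opaque identifier of the medical center; unique within an extract
center_category,character,FALSE,"Center category: GH_NFPH (general / non-for-profit hospital), UH (university hospital), CCC (comprehensive cancer center), PH (private hospital)"
center_region,character,FALSE,"Geographic region: North, East, SouthEast, SouthWest, West, ParisArea"
patient_id,character,TRUE,Hospital patient identifier; unique within a center only
birth_year,integer,FALSE,Year of birth
gender,character,FALSE,F or M
weight,double,FALSE,Weight in kg
height,double,FALSE,Height in cm
ecog,integer,FALSE,ECOG performance status 0-4
diagnosis,character,FALSE,"Primary cancer diagnosis: breast_cancer, lung_cancer, other"
disease_stage,character,FALSE,"Disease stage: early, locally_advanced, metastatic"
metastasis_sites,character,FALSE,Semicolon-separated metastasis site codes
oncogenic_driver,character,FALSE,Oncogenic driver / biomarker code (e.g. HER2, EGFR, ALK, PD-L1)
drug_raw,character,TRUE,Drug name as entered in the pharmacy record (free text; brand or INN)
drug_inn,character,FALSE,Standardized International Nonproprietary Name (filled by codification)
drug_brand,character,FALSE,Brand name as entered
dose,double,TRUE,Administered dose in mg; must be > 0
administration_date,date,TRUE,Calendar date of administration (ISO-8601)
treatment_line,integer,FALSE,Treatment line (>= 1) within the current disease phase
cycle_number,integer,FALSE,Incremental cycle number within the regimen (>= 1)
frequency_days,integer,FALSE,Days between cycles
regimen_label,character,FALSE,Free-text regimen / protocol label
estimated_duration_days,integer,FALSE,Estimated duration of the regimen in days
response,character,FALSE,"Disease assessment result: CR, PR, SD, PD"
response_date,date,FALSE,Date of disease assessment
discontinuation_motive,character,FALSE,Treatment discontinuation motive (free text)
discontinuation_date,date,FALSE,Treatment discontinuation date
trial_name,character,FALSE,Clinical trial name if the patient is enrolled
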