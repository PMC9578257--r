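# Column schemas of the claims-bundle CSV files (documented order).
# Dates are ISO-8601 calendar dates; money columns are EUR >= 0.
patients.csv:
  ssn: opaque national identifier (pre-linkage only)
  patient_id: final pseudonym (empty pre-linkage)
  birth_year: integer year
  sex: F | M
  vulnerable: socio-economic vulnerability marker (TRUE/FALSE)
  scheme: ffs | capitation (capitation only in multi_capitation practices)
  practice_id: foreign key -> practices.csv
  region: categorical label
practices.csv:
  practice_id: identifier
  ptype: mono_ffs | multi_ffs | multi_capitation
  region: categorical label
  n_gps: positive integer, equals number of entries in gp_ids
  gp_ids: semicolon-separated GP identifiers
claims.csv:
  event_id: identifier
  patient_fk: foreign key -> patients.csv (ssn pre-linkage)
  category: gp_visit | dietician_consult | diabetes_education | foot_exam |
    ophthalmologist_visit | lab_test_billed | prediabetes_pass |
    t1d_convention | insulin_pump | other
  analyte: analyte of a billed lab test (empty otherwise)
  date: ISO-8601 date
  prescriber_cat: gp | specialist | other
  cost_ziv: reimbursed amount
  cost_pers: personal contribution
  suppl: supplement
pharma.csv:
  event_id: identifier
  patient_fk: foreign key -> patients.csv
  atc_code: ATC code (A10BA -> metformin, A10BB -> sulfonylurea, A10A -> insulin)
  drug_class: metformin | sulfonylurea | insulin | other
  date: dispense date
  prescriber_cat: gp | specialist | other
  cost_ziv: reimbursed amount
  cost_pers: personal contribution
  suppl: supplement
labs.csv:
  result_id: identifier
  lab_id: foreign key -> lab_registry.csv
  lab_patient_key: opaque lab-side patient identifier
  loinc_code: LOINC code of the analyte
  analyte: hba1c | ldl_c | total_chol | hdl_c | triglycerides | creatinine |
    albuminuria | glucose
  value: numeric result (hba1c in mmol/mol, creatinine in mg/dL)
  units: unit matched to the analyte
  date: sampling date
hospital.csv:
  event_id: identifier
  patient_fk: foreign key -> patients.csv
  admit_date: admission date
  discharge_date: discharge date (>= admit_date)
  cost_ziv: reimbursed amount
lab_registry.csv:
  lab_id: identifier
  participating: whether the lab delivers data (TRUE/FALSE)
lab_keymap.csv:
  lab_id: identifier
  lab_patient_key: lab-side identifier
  ssn: national identifier (lab/TTP custody only; never researcher-facing)
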