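# Example run configuration for the ds-phenotype command-line wrapper.
study_end: 2020-12-31
confidence: 0.95
codes:
  icd9_codes: ["758.0"]
  icd10_codes: ["Q90"]
simulation:
  seed: 20260101
  n_children: 2000
  ds_prevalence: 0.10
  birth_year_range: [2000, 2017]
  bc_sensitivity: 0.28
  bc_confirmed_fraction: 0.35
  bc_false_positive_rate: 0.002
  ds_visit_rate: 2.0
  miscode_rate: 0.02
  background_visit_rate: 3.0
  followup_censor_prob: 0.2
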