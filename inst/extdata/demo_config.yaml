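# Packaged demo configuration: a small two-wave synthetic study with the two
# most widely used screening instruments, no injected errors.
timestamp: "2024-01-01T00:00:00Z"
study:
  study_id: demo_study
  n_households: 20
  n_individuals: 50
  n_waves: 2
  instruments: ["PHQ-9", "GAD-7"]
  covariates: ["employment_status", "education_level"]
  item_missingness: 0.05
  demographic_missingness: 0
  first_wave_date: "2020-01-15"
  wave_interval_days: 182
  reference_date: "2024-01-01"
  seed: 20
etl:
  reference_date: "2024-01-01"
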