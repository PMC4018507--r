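population:
  total: 33000000.0
  shape: england_like
natural_history:
  anchor_ages:
  - 30.0
  - 50.0
  - 70.0
  - 100.0
  adenoma_onset:
  - 0.021
  - 0.02
  - 0.045
  - 0.011
  lr_to_hr:
  - 0.009
  - 0.008
  - 0.008
  - 0.004
  hr_to_crcA:
  - 0.029
  - 0.025
  - 0.054
  - 0.115
  normal_to_crcA: 4.0e-05
  stage_progression:
    A: 0.51
    B: 0.69
    C: 0.71
  presentation:
    A: 0.04
    B: 0.18
    C: 0.37
    D: 0.74
  proximal_fraction: 0.38
  adenomas_per_carrier: 1.9
  advanced_hr_fraction: 0.75
tests:
  gfobt_sens:
    LR: 0.01
    HR: 0.12
    CRC: 0.24
  gfobt_spec_ages:
  - 50.0
  - 70.0
  gfobt_spec:
  - 0.99
  - 0.97
  col_sens:
    LR: 0.77
    HR: 0.98
    CRC: 0.98
  col_spec: 1.0
behaviour:
  per_round_uptake: 0.54
  ever_participation: 0.63
  col_followup_compliance: 0.79
  col_surveillance_compliance: 0.83
  repeat_test_rate: 0.07
  mean_tests_completed: 1.08
adverse_events:
  perforation_prob_polypectomy: 0.003
  perforation_prob_no_polypectomy: 0.0
  death_given_perforation: 0.052
  bleed_hospitalisation_prob: 0.003
  perforation_cost: 5089.0
  bleed_cost: 278.0
economics:
  utility_cancer_free: 0.8
  utility_crc: 0.7
  discount_rate: 0.035
  wtp_threshold: 20000.0
  treatment_cost_min:
    A: 1320.0
    B: 1479.0
    C: 1493.0
    D: 772.0
  treatment_cost_max:
    A: 8375.0
    B: 8362.0
    C: 13862.0
    D: 11198.0
  treatment_cost_age_direction: max_at_youngest
  screening_costs:
    gfobt_noncomplier: 2.03
    gfobt_normal: 3.36
    gfobt_positive: 11.94
    colonoscopy: 563.0
    pathology: 26.0
campaign:
  stage_multipliers:
    A: 0.1
    B: 0.1
    C: 0.1
    D: 0.1
  duration_months: 1.0
  campaign_cost_per_person: 0.14
  gp_attendances_per_person: 0.0014
  secondary_appointments_per_person: 1.52606e-05
  gp_visit_cost: 36.0
  secondary_visit_cost: 200.0
  proportion_additional: 0.5
  population: ~
screening:
  enabled: yes
  start_age: 60.0
  end_age: 69.0
  interval_years: 2.0
  surveillance_interval_years: 3.0
model:
  max_age: 100.0
  half_cycle_correction: no
  survival_preset: default
  stage_distribution:
    A: 0.11
    B: 0.25
    C: 0.36
    D: 0.29
experiments:
  run: base_case
  grid_durations:
  - 1.0
  - 3.0
  - 6.0
  grid_magnitudes:
  - 0.05
  - 0.1
  - 0.2
  stage_restricted: no
  psa_samples: 1000.0
  psa_rel_se: 0.1
pilot:
  n_months: 24.0
  baseline_mean: 300.0
  step_month_index: 14.0
  step_multiplier: 1.1
  n_regions: 2.0
  test_month: 14.0
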