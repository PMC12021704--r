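# Default model configuration. All quantities are overridable; the
# synthetic cohort section reproduces the published baseline
# characteristics of the trial population.
seed: 1
n_years: 45
attrition: 0.31
n_boot: 5000

cohort:
  n: 100000
  p_male: 0.478
  p_duration_lt1: 0.545
  imd_probs: [0.155, 0.159, 0.243, 0.222, 0.222]
  p_smoker: 0.15
  p_glucose_med: 0.55
  p_statin: 0.55
  p_antihypertensive: 0.50
  continuous:
    age:        {mean: 59.8,  sd: 12.6, lower: 18,  upper: 95}
    bmi:        {mean: 34.6,  sd: 6.8,  lower: 25,  upper: 70}
    weight:     {mean: 97.8,  sd: 20.5, lower: 45,  upper: 250}
    hba1c:      {mean: 53.9,  sd: 13.6, lower: 30,  upper: 130}
    sbp:        {mean: 134.5, sd: 17.3, lower: 80,  upper: 220}
    dbp:        {mean: 80.8,  sd: 10.0, lower: 40,  upper: 140}
    total_chol: {mean: 4.74,  sd: 1.1,  lower: 1.5, upper: 12}
    hdl:        {mean: 1.25,  sd: 0.5,  lower: 0.4, upper: 4}
    ldl:        {mean: 2.53,  sd: 0.9,  lower: 0.5, upper: 8}
  # correlation defaults: weight-bmi 0.9, bmi-sbp 0.2, all others 0.1;
  # override pairs here, e.g.
  # correlation_overrides:
  #   - {a: hba1c, b: bmi, value: 0.15}

# Arm differences (DEW minus DE) and decay horizons
effects:
  hba1c_effect_12m: -0.84
  weight_effect_12m: -1.38
  hba1c_effect_6m: -1.83
  weight_effect_6m: -1.77
  hba1c_decay_horizon: 5
  bmi_decay_horizon: 10
  decay_shape: linear

# Common annual risk-factor drift (both arms)
drift:
  hba1c: 0.5
  bmi: 0
  sbp: 0
  chol_hdl_ratio: 0

psa:
  n_samples: 2000
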