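# SYNTHETIC, ILLUSTRATIVE risk-equation parameters.
#
# These coefficients are NOT the published coefficients of any diabetes
# outcomes model; they were chosen to produce epidemiologically plausible
# annual incidences for a population with recently diagnosed type 2
# diabetes (mean age ~60), so the simulation machinery can be exercised
# and tested end to end. Substitute published coefficient sets for
# substantive work.
#
# Hazard structure per equation:
#   H = calibration_multiplier * prod(active treatment RRs) * base(form)
#   exponential: base = exp(intercept + sum(coef * covariate))
#   weibull:     base = exp(lp) * ((d+1)^shape - d^shape), d = duration
#   gompertz:    base = exp(lp) * (exp(shape*(a+1)) - exp(shape*a))/shape
#   annual event probability = 1 - exp(-H)
equations:
  - outcome: mi
    form: weibull
    shape: 1.3
    intercept: -12.8
    coefficients:
      hba1c: 0.030
      sbp: 0.010
      chol_hdl_ratio: 0.150
      age: 0.060
      male: 0.400
      smoker: 0.350
    treatment_rr: {statin: 0.75, antihypertensive: 0.85}
  - outcome: stroke
    form: weibull
    shape: 1.2
    intercept: -14.1
    coefficients:
      hba1c: 0.025
      sbp: 0.018
      age: 0.070
      male: 0.200
      smoker: 0.400
      hist_mi: 0.500
    treatment_rr: {statin: 0.85, antihypertensive: 0.75}
  - outcome: chf
    form: gompertz
    shape: 0.08
    intercept: -12.6
    coefficients:
      hba1c: 0.020
      bmi: 0.040
      hist_mi: 0.900
    treatment_rr: {statin: 1.0, antihypertensive: 0.85}
  - outcome: ihd
    form: exponential
    intercept: -9.2
    coefficients:
      hba1c: 0.025
      chol_hdl_ratio: 0.200
      age: 0.030
      male: 0.300
  - outcome: amputation
    form: exponential
    intercept: -11.0
    coefficients:
      hba1c: 0.045
      smoker: 0.400
  - outcome: blindness
    form: exponential
    intercept: -10.2
    coefficients:
      hba1c: 0.035
      sbp: 0.008
  - outcome: ulcer
    form: exponential
    intercept: -10.0
    coefficients:
      hba1c: 0.040
  - outcome: renal_failure
    form: exponential
    intercept: -12.0
    coefficients:
      hba1c: 0.040
      sbp: 0.012
  - outcome: death
    form: gompertz
    shape: 0.095
    intercept: -11.25
    coefficients:
      hba1c: 0.010
      bmi: 0.012
      male: 0.150
      smoker: 0.300
      hist_mi: 0.500
      hist_stroke: 0.600
      hist_chf: 0.700
      hist_renal_failure: 1.000
    treatment_rr: {statin: 0.90, antihypertensive: 0.95}
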