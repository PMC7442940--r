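# Office-based variant of the general-CVD Framingham equations: body
# mass index replaces the lipid terms, so no blood test is required.
model: framingham-general-cvd-bmi
horizon_years: 10
lipid_units: mmol/L
family_history_hazard_multiplier: 1.0
ideal:
  sbp: 120.0
  total_cholesterol: 4.0
  hdl_cholesterol: 1.3
  bmi: 22.0   # kg/m^2, mid healthy range
female:
  s0: 0.94833
  mean_linear_predictor: 26.0145
  terms:
    - {covariate: age,      transform: log, beta: 2.72107}
    - {covariate: bmi,      transform: log, beta: 0.51125}
    - {covariate: sbp,      transform: log, beta: 2.81291, when_treated: false}
    - {covariate: sbp,      transform: log, beta: 2.88267, when_treated: true}
    - {covariate: smoker,   transform: identity, beta: 0.61868}
    - {covariate: diabetes, transform: identity, beta: 0.77763}
male:
  s0: 0.88431
  mean_linear_predictor: 23.9388
  terms:
    - {covariate: age,      transform: log, beta: 3.11296}
    - {covariate: bmi,      transform: log, beta: 0.79277}
    - {covariate: sbp,      transform: log, beta: 1.85508, when_treated: false}
    - {covariate: sbp,      transform: log, beta: 1.92672, when_treated: true}
    - {covariate: smoker,   transform: identity, beta: 0.70953}
    - {covariate: diabetes, transform: identity, beta: 0.53160}
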