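# Default coefficient set: general-CVD Framingham risk equations
# (sex-specific Cox models, lipid-based, 10-year horizon).
# Lipid betas were published on the mg/dL scale; user inputs in mmol/L
# are converted with 38.67 mg/dL per mmol/L before transforming.
# REPLACEABLE: deployed national calculators recalibrate some weightings
# for local guidelines; load a modified file via load_coefficients().
model: framingham-general-cvd-lipid
horizon_years: 10
lipid_units: mg/dL
family_history_hazard_multiplier: 1.0
ideal:
  sbp: 120.0            # mmHg, untreated
  total_cholesterol: 4.0 # mmol/L
  hdl_cholesterol: 1.3   # mmol/L (~50 mg/dL), population-typical ideal
female:
  s0: 0.95012
  mean_linear_predictor: 26.1931
  terms:
    - {covariate: age,               transform: log, beta: 2.32888}
    - {covariate: total_cholesterol, transform: log, beta: 1.20904}
    - {covariate: hdl_cholesterol,   transform: log, beta: -0.70833}
    - {covariate: sbp,               transform: log, beta: 2.76157, when_treated: false}
    - {covariate: sbp,               transform: log, beta: 2.82263, when_treated: true}
    - {covariate: smoker,            transform: identity, beta: 0.52873}
    - {covariate: diabetes,          transform: identity, beta: 0.69154}
male:
  s0: 0.88936
  mean_linear_predictor: 23.9802
  terms:
    - {covariate: age,               transform: log, beta: 3.06117}
    - {covariate: total_cholesterol, transform: log, beta: 1.12370}
    - {covariate: hdl_cholesterol,   transform: log, beta: -0.93263}
    - {covariate: sbp,               transform: log, beta: 1.93303, when_treated: false}
    - {covariate: sbp,               transform: log, beta: 1.99881, when_treated: true}
    - {covariate: smoker,            transform: identity, beta: 0.65451}
    - {covariate: diabetes,          transform: identity, beta: 0.57367}
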