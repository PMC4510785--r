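# SYNTHETIC risk-equation set for the annual-cycle outcomes microsimulation.
# These coefficients are NOT the licensed published model's values; they are
# a synthetic stand-in with physiologically-signed covariate effects, loosely
# calibrated so routine-care 30-year cumulative incidences are plausible for
# a screen-detected type 2 diabetes cohort. For method development and
# testing only.
paths:
  hba1c: {intercept: 0.651, baseline: 0.0, duration: 0.0, lag: 0.93}
  sbp: {intercept: 14.45, baseline: 0.0, duration: 0.0, lag: 0.90}
  chol: {intercept: 0.50, baseline: 0.0, duration: 0.0, lag: 0.90}
  hdl: {intercept: 0.12, baseline: 0.0, duration: 0.0, lag: 0.90}
  smoker: {intercept: 0.0, baseline: 0.0, duration: 0.0, lag: 0.97}
events:
  mi:
    link: logistic
    coef: {intercept: -7.461, age_diag: 0.03, female: -0.45, afro: -0.25,
           asian: 0.25, duration: 0.025, hba1c: 0.10, sbp: 0.010, chol: 0.11,
           hdl: -0.65, smoker: 0.35, hist_ihd: 0.5, hist_stroke: 0.25,
           hist_heart_failure: 0.3}
  stroke:
    link: logistic
    coef: {intercept: -10.261, age_diag: 0.045, female: -0.2, duration: 0.03,
           hba1c: 0.08, sbp: 0.015, smoker: 0.4, hist_mi: 0.3}
  ihd:
    link: logistic
    coef: {intercept: -7.538, age_diag: 0.025, female: -0.3, duration: 0.02,
           hba1c: 0.08, sbp: 0.006, chol: 0.15, hdl: -0.8, smoker: 0.3}
  heart_failure:
    link: weibull
    shape: 1.3
    coef: {intercept: -10.5, age_diag: 0.05, female: 0.1, sbp: 0.010,
           hba1c: 0.08, hist_mi: 0.8, hist_ihd: 0.4}
  amputation:
    link: logistic
    coef: {intercept: -9.24, age_diag: 0.02, duration: 0.05, hba1c: 0.15,
           smoker: 0.4}
  blindness:
    link: logistic
    coef: {intercept: -9.38, age_diag: 0.02, duration: 0.04, hba1c: 0.18,
           sbp: 0.008}
  renal_failure:
    link: logistic
    coef: {intercept: -10.04, duration: 0.06, sbp: 0.012, hba1c: 0.12}
  diabetes_death:
    link: logistic
    coef: {intercept: -10.434, age_diag: 0.06, duration: 0.06, hba1c: 0.12,
           smoker: 0.3, hist_mi: 0.9, hist_stroke: 0.7,
           hist_heart_failure: 0.8, hist_renal_failure: 1.2,
           hist_amputation: 0.6}
  other_death:
    link: weibull
    shape: 1.5
    coef: {intercept: -9.535, age_diag: 0.085, female: -0.15, smoker: 0.4}
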