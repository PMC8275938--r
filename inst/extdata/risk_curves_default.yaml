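# Default injury-risk-curve parameters.
#
# These are synthetic approximations of the shapes of brain-injury risk
# curves published in the SIMon literature, NOT the published parameter
# sets (which are not redistributed here). They exist so that risk_report()
# runs out of the box; replace with your own parameterisation for any
# quantitative use.
- criterion: CSDM_0.15
  injury_type: DAI
  form: logistic
  params: {intercept: -2.0, slope: 4.0}
- criterion: CSDM_0.25
  injury_type: DAI
  form: logistic
  params: {intercept: -2.2, slope: 4.5}
- criterion: MPS
  injury_type: DAI
  form: logistic
  params: {intercept: -3.0, slope: 3.5}
- criterion: MPS
  injury_type: contusion
  form: logistic
  params: {intercept: -3.5, slope: 3.0}
- criterion: DDM
  injury_type: contusion
  form: weibull
  params: {scale: 0.5, shape: 1.2}
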