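# Example run configuration: published defaults for every section.
reference:
  lambda_age_grouping: num_cmg
parameters:
  theta:
    lambda0: 0.216
    d0: 0.477
    p0: 0.207
    x0: 168.0
    lambda_h: 133.0
    lambda_r: 9.66
  omega: [1.57, 1.62, 0.251, 1.31, 1.27, 1.22]
  sigma2: 0.219
covariates:
- covariate: alemtuzumab
  parameter: x0
  effect: -0.828
estimation:
  n_samples: 200
  max_iter: 60
forecast:
  cutoff_days: 183
  n_samples: 500
  horizon_days: 1095
seeds:
  base: 1
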