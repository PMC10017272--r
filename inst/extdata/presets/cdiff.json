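{
  "name": "cdiff",
  "n_samples": 157493,
  "n_covariates": 25,
  "prevalence": 0.01,
  "coefficients": null,
  "covariate_model": "standard_normal"
}
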