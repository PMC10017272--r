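{
  "name": "edin",
  "n_samples": 1253,
  "n_covariates": 9,
  "prevalence": 0.219,
  "coefficients": null,
  "covariate_model": "standard_normal"
}
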