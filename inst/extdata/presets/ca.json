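{
  "name": "ca",
  "n_samples": 141,
  "n_covariates": 2,
  "prevalence": 0.638,
  "coefficients": null,
  "covariate_model": "standard_normal"
}
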