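# Default synthetic pipeline configuration: two groups of 15, both run
# conditions, published-table ground truth, moderate innovation noise.
mode: synthetic
seed: 1
n_per_group: 15
noise_sd: 0.2
conditions: [Pain, No-Pain]
subregions: signal
alpha_family: 0.05
covariate: first_pain
n_null: 10
fit_opts:
  n_latent_basis: 12
  max_iter: 200
  tol: 1.0e-6
  n_restarts: 5
  seed: 1
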