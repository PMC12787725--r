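# Demo configuration: synthetic dataset with packaged defaults.
# The screening section is mandatory -- no standard is assumed silently.
seed: 1
generator:
  soil_cv: 0.05
  tissue_noise_sd: 0.1
  n_replicates: 4
screening:
  source: backcalc
monte_carlo:
  n: 2000
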