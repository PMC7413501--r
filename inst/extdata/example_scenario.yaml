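# Small two-group turbidometric-reader scenario: a well-growing glucose
# group against the no-added-carbon control.
system: BSC
replicate_cv: 0.05
groups:
  - strain: KF657
    substrate: glucose
    n_replicates: 3
    spec:
      mu_true: 0.07
      lag_true: 40
      A_true: 2.08
      baseline_od: 0.1
      noise_sd: 0.004
      sampling_interval: 0.5
  - strain: KF657
    substrate: no_carbon
    n_replicates: 3
    spec:
      mu_true: 0.01
      lag_true: 80
      A_true: 0.4
      baseline_od: 0.1
      noise_sd: 0.004
      sampling_interval: 0.5
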