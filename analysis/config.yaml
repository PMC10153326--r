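n_participants: 1500
seed: 20140602
sleep:
  mean_onset_clock: 23.0
  mean_duration: 8.0
  sigma_onset_range: [0.1, 2.5]
  sigma_duration_range: [0.1, 1.5]
  between_onset_sd: 1.0
  between_duration_sd: 0.5
  waso_rate: 2.0
  waso_bout_mean: 15.0
  nonwear_prob: 0.05
  nonwear_len: 4.0
  n_days: 7
  epoch_len: 30
metrics:
  min_pair_fraction: 0.8
hazard:
  type: ushape
  baseline_rate: 0.03
  admin_censor: 7.1
missing:
  rate: 0.02
  columns: [townsend, pack_years, income]
imputation:
  m: 5
  k_donors: 5
  n_iter: 5
models:
  covariate_set: primary
  outcome: all
  interval_len: 0.25
  bootstrap_B: 200
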