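# Demo cohort: 5 groups x 4 subjects, 40 trials each; runs in minutes.
cohort:
  group_sizes:
    Responding: 4
    Passive: 4
    AsleepNREM: 4
    MCS: 4
    UWS: 4
  n_change_trials_per_time: 8
  n_sham_trials: 16
  sampling_rate: 1024
electrode:
  n_perm: 1000
  cluster_alpha: 0.05
pcia:
  window: [-0.5, 1.5]
  target_rate: 64
classify:
  features: [p2_amplitude, pcia_onset, pcia_change]
  shrinkage: 0
  n_shuffles: 0
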