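# Example experiment configuration (YAML; JSON is accepted too).
engine:
  grid: {gain_count: 12, freq_count: 10, bw_count: 6, trunc_count: 5}
  stimuli: {freq_count: 15, contrast_count: 13}
  psy: {guess: 0.1, lapse: 0.04, slope: 3.5, letters_per_trial: 3}
cohort:
  group: MS
  n_subjects: 44
  n_single_eye: 1
experiment:
  n_trials: 25
  seed: 1
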