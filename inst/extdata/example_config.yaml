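# Example pipeline configuration: a reduced cohort for a quick end-to-end
# run. Omitted keys keep the package defaults (3 classes, 7 cued reps,
# 30 free trials, C = 1, searchlight radius 1, n_select 100, p0 derived,
# alpha 0.001).
grid_shape: [20, 20, 20]
n_subjects: 3
design:
  cued_reps_per_class: 3
  free_trials: 9
signal:
  effect_size: 1.5
searchlight:
  n_select: 50
seed: 7
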