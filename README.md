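# episearch

Searchlight decoding of episodic memory patterns from fMRI, with group
overlap maps — a tested, reusable R implementation of the full analysis
chain used to ask whether individual episodic memories leave decodable
multivoxel traces in the medial temporal lobe.

## The problem and who this is for

In an episodic-recall experiment, a participant repeatedly recalls one of
three well-learned everyday memories in the scanner: a cued block of 21
trials (seven per memory, no memory twice in a row), then a free-recall
block of 30 trials. Multivariate pattern analysis (MVPA) asks whether the
recalled memory can be predicted from the joint BOLD pattern across voxels
in an anatomical ROI — hippocampus (HC), entorhinal cortex (EC),
parahippocampal gyrus (PHG). Above-chance decoding is evidence that the
region carries a stable trace of each individual memory; the spatial
consistency of that information across subjects is assessed with a group
frequency map and voxelwise binomial tests.

The package is for methodologists and students who want the complete
pipeline — simulation with ground truth, preprocessing, leakage-safe nested
feature selection, SVM decoding, permutation chance estimates, and group
inference — as composable, deterministic R functions with a test-suite that
checks every numerical contract against independent oracles.

## The method in brief

* **Decoder**: linear soft-margin SVM, fixed `C = 1`, minimizing
  `½‖w‖² + C Σ max(0, 1 − yᵢ(w·xᵢ + b))`; multiclass by one-vs-one pairwise
  voting with deterministic tie-breaks (summed margin, then lowest class).
* **Cross-validation**: leave-one-trial-out (k = number of trials). Within
  each fold, **searchlight feature selection** — every ROI voxel scored by
  inner 5-fold CV accuracy of its 27-voxel neighborhood, top `n_select`
  kept — runs on training trials only, so accuracies are leakage-free.
  Whole-data selection is available strictly as a diagnostic of
  double-dipping bias.
* **Chance**: label permutations within condition, full pipeline re-run per
  permutation; three balanced classes give chance 0.33.
* **Group maps**: subject information maps summed into a frequency heat map
  (max = number of subjects); voxelwise p = inclusive upper binomial tail
  `P(X ≥ k)` with null selection probability `p0 = n_select / |ROI|`,
  thresholded uncorrected at p < 0.001.
* **Simulation**: 4D runs = baseline + linear drift + Gaussian noise +
  class-specific ±effect patterns over clustered informative voxels in a
  delayed boxcar window; cohorts share cluster locations to a configurable
  degree, so group overlap has a known ground truth.

See `vignettes/decoding-pipeline.Rmd` for the full methods account.

## Worked example

Simulate one subject at the study design, preprocess, and run the nested
decoding analysis on the hippocampus-analog ROI:

```r
library(episearch)

masks   <- generate_roi_masks(c(20, 20, 20))          # HC, EC, PHG analogs
design  <- generate_trial_design(design_config(seed = 42))
design
#> <trial_design: 51 trials (21 cued, 30 free), 3 classes, 219 volumes>

sim      <- synthesize_run(design, masks$HC, signal_config(seed = 42))
run      <- linear_detrend(sim$run)
patterns <- extract_trial_patterns(run, shift_onsets(design, 2, 2),
                                   masks$HC, 2)
patterns
#> <pattern_set 'HC': 51 trials x 224 voxels, 3 classes>

result <- cross_validate_decoding(patterns, masks$HC)
glance(result)
#> # A tibble: 1 x 8
#>   roi   accuracy n_trials n_classes chance n_select selection condition
#> 1 HC       0.941       51         3  0.333      100 nested    both

result$confusion
#>     predicted
#> true  1  2  3
#>    1 13  0  1
#>    2  0 23  1
#>    3  0  1 12
```

48 of 51 held-out trials are predicted correctly (accuracy 0.941 against
chance 0.333): each trial was decoded by a model that never saw it — not
even during feature selection. The row sums of the confusion matrix are the
true per-class trial counts (the free-recall block is intentionally
imbalanced, as a free-choice condition would be). `result$information_map`
holds the 100 voxels carrying the most episodic information;
`autoplot(result$score_map)` shows the searchlight score landscape, and for
a cohort, `aggregate_heat_map()` + `binomial_voxel_pvalues()` +
`threshold_map()` produce the group overlap inference. The end-to-end
version of all of this is `run_pipeline(pipeline_config(), "results/")`.

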