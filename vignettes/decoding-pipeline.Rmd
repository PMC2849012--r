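---
title: "Searchlight decoding of episodic memory patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight decoding of episodic memory patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episearch)
```

## The analysis problem

Multivariate pattern analysis (MVPA) of fMRI asks whether a cognitive state
can be decoded from the *joint* pattern of BOLD signal across many voxels,
rather than from voxel-by-voxel statistics. The setting this package
implements is episodic-memory decoding in the medial temporal lobe: a
participant repeatedly recalls one of three well-learned everyday memories
inside the scanner — first in a cued-recall block of 21 trials (seven per
memory, pseudorandomly ordered so the same memory never occurs twice in a
row), then, after a rest gap, in a free-recall block of 30 trials where the
participant chooses which memory to recall, with every memory sampled at
least once. Decoding which memory is being recalled from the voxel pattern
in an anatomical region of interest (ROI) — hippocampus (HC), entorhinal
cortex (EC), or parahippocampal gyrus (PHG) — is evidence that the region
carries a stable, distinguishable trace of each individual memory.

The pipeline has five stages, each an exported function group:

1. **simulate** — synthetic cohorts with known ground truth
   (`generate_trial_design()`, `generate_roi_masks()`, `synthesize_run()`,
   `generate_cohort()`);
2. **preprocess** — linear detrending, hemodynamic onset shift, trial
   pattern extraction (`linear_detrend()`, `shift_onsets()`,
   `extract_trial_patterns()`);
3. **searchlight feature selection** — local decodability scores and
   per-subject information maps (`score_searchlights()`,
   `build_information_map()`);
4. **decoding** — nested leave-one-trial-out cross-validation of a
   one-vs-one linear SVM, with permutation estimates of chance
   (`cross_validate_decoding()`, `permutation_chance()`);
5. **group maps** — frequency heat maps across subjects and voxelwise
   binomial tests (`aggregate_heat_map()`, `binomial_voxel_pvalues()`,
   `threshold_map()`).

`run_pipeline()` chains all five on a validated `pipeline_config()` and
writes every artifact (NIfTI volumes, TSV tables, JSON summaries, the
resolved configuration and a parameter log) into a results directory.

## The decoder

The classifier is a linear soft-margin support vector machine with the
regularization hyperparameter fixed at $C = 1$ — no hyperparameter search.
For a binary problem with labels $y_i \in \{-1, +1\}$ it minimizes

$$\tfrac{1}{2}\lVert w \rVert^2 + C \sum_i \max\bigl(0,\; 1 - y_i (w \cdot x_i + b)\bigr).$$

Multiclass problems use the standard one-vs-one extension: one binary SVM
per unordered class pair, prediction by majority vote. Vote ties are broken
deterministically — largest summed signed pairwise decision margin, then
lowest class id — so repeated runs are bit-identical.

The solver is dual coordinate descent on the L1-loss dual, with the bias
absorbed into an augmented constant feature (so it is weakly regularized
with $w$; the convention of fast linear-SVM solvers). Sweeps visit samples
in a pseudo-random order drawn from a fixed, deterministically seeded
stream: this converges several-fold faster than cyclic order while keeping
results exactly reproducible. Convergence is declared when the largest
projected gradient falls below `tol` (default `1e-4`); non-convergence
within `max_iter` sweeps is flagged in the fitted object, never silent.
The test-suite validates the solver against separable-cloud and
duplicated-column oracles and cross-checks it against the libsvm
implementation in `e1071` on toy problems; the cross-check is an
independent oracle, not the implementation.

The nested searchlight scheme fits on the order of $10^5$ small SVMs per
subject (51 outer folds × ~200 voxels × 5 inner folds × 3 class pairs),
which is why the inner loops are compiled code: a full nested analysis of
one subject at the default scale takes roughly 10–15 s on one CPU, and a
20-permutation chance calibration a few minutes.

## Cross-validation, feature selection, and leakage

The outer testing regime is **leave-one-trial-out**: $k$-fold
cross-validation with $k$ equal to the number of trials (51 for the default
design, cued and free conditions collapsed). Within every outer fold,
feature selection runs **on the training trials only**:

1. every ROI voxel is scored by the cross-validated accuracy of a one-vs-one
   linear SVM restricted to the voxel's searchlight neighborhood (stratified
   5-fold inner CV on the training trials);
2. the `n_select` top-scoring voxels form the fold's feature set (ties broken
   by lexicographic voxel index);
3. voxels are z-scored with training-fold means and standard deviations;
4. the SVM is trained on the training trials and the held-out trial is
   predicted.

Because the held-out trial never influences scoring, selection, or scaling,
the reported accuracy is leakage-free. The package also exposes
`selection = "whole"`, which deliberately selects features on *all* trials.
It exists to demonstrate why nesting matters: on label-permuted null data
the nested scheme stays inside the 95% binomial band around $1/3$, while
whole-data selection inflates accuracy well above it (~0.41 on average in
the test-suite's fixed-seed runs, individual runs up to 0.53). It must
never be used for inference, and the test-suite asserts both behaviours.

The subject's reported **information map** — the `n_select` voxels carrying
the most episodic information — is recomputed from all trials. It is the
map used for group analysis and display, never for accuracy.

Chance performance is estimated by `permutation_chance()`: class labels are
shuffled *within condition* (cued among cued, free among free), the entire
nested pipeline is re-run per permutation, and the empirical p-value is
$(1 + \#\{\text{null} \ge \text{observed}\}) / (n_\text{perm} + 1)$.

## Group-level inference

Subject information maps (binary, on the common grid) are summed into a
frequency heat map: the value at a voxel is the number of subjects (0–10)
whose map contains it. Under a null in which each subject selects uniformly
at random within the ROI, a voxel's frequency $k$ is
$\mathrm{Binomial}(n, p_0)$ with $p_0 = n_\text{select} / |\mathrm{ROI}|$;
the voxelwise p-value is the inclusive upper tail $P(X \ge k)$, computed by
exact summation of the mass function. Thresholding is strict and
uncorrected at $\alpha = 0.001$ by default, with an optional Bonferroni
flag. $p_0$ is a required, logged parameter: which frequency counts pass
any threshold depends directly on it, so it is never silently assumed.

A note on recovery geometry: with the default
$p_0 = 100/224 \approx 0.45$ and ten subjects, only voxels selected by
*all ten* subjects pass $p < 0.001$ ($0.45^{10} \approx 3\times10^{-4}$,
while $P(X \ge 9) \approx 0.004$). The significant set is therefore the
high-confidence core of the shared signal territory: in the shared-cluster
recovery simulation it sits entirely inside the implanted-plus-halo
territory (precision 1.0) and contains the implanted voxels themselves,
but it is necessarily much smaller than the full identifiable territory,
so set-similarity indices like Jaccard against that territory plateau
around 0.3–0.5. The acceptance suite asserts the containment form of
recovery for exactly this reason.

For externally supplied maps on different grids,
`resample_information_map()` provides nearest-neighbor affine resampling
onto the common grid; nonlinear stereotactic normalization of real
anatomies is out of scope.

## What the synthetic generator emulates — and what it does not

`synthesize_run()` builds a 4D run as

$$\text{baseline} + \text{drift}\cdot t + \mathcal{N}(0, \sigma^2)
  \;+\; \text{class pattern over informative voxels during trial windows}.$$

* **Design**: 3 classes, 21 cued + 30 free trials, onsets every 4 volumes
  (14 s at TR 3.5 s), a 9-volume (~30 s) rest gap between blocks, run-length
  padding after the last trial. Cued orders are drawn by a greedy sampler
  with a feasibility look-ahead, so the no-immediate-repeat constraint is
  satisfied for every feasible configuration rather than by rejection.
  Free-recall labels place one trial of each class and draw the remainder
  uniformly, then shuffle the block — every class is guaranteed to occur,
  imbalance is allowed and recorded, matching a participant free to choose.
* **Signal**: each class has a fixed spatial pattern of $\pm$`effect_size`
  over the informative voxels (independent random signs per voxel and
  class — orthogonal in expectation, re-drawn in the measure-zero event of
  duplicate patterns — so pairwise discriminability scales with
  `effect_size`). Informative voxels are the union of
  `n_informative_clusters` small Euclidean balls centered at ROI voxels;
  cohorts draw cluster centers from a common prior with a configurable
  shared fraction, which makes expected group overlap controllable from
  fully shared to independent.
* **Response model**: the pattern is added as a boxcar over
  `pattern_window_volumes` volumes starting `hemodynamic_delay_volumes`
  after onset. There is no hemodynamic convolution — deliberately. The
  pipeline only ever consumes window averages, so a boxcar carries the same
  information while keeping the arithmetic oracles in the tests exact.
* **Not modeled**: realistic hemodynamic response shapes, physiological and
  temporally autocorrelated noise, motion, multi-run sessions, anatomical
  variability between subjects. Passing tests therefore demonstrate that the
  *analysis machinery* is correct and calibrated — they do not certify
  performance on real scanner data, where noise structure and registration
  error matter.

## Parameters, defaults, and why

| Parameter | Default | Rationale |
|---|---|---|
| `tr_s` | 3.5 s | the acquisition this design emulates |
| `voxel_size_mm` | 1.5 | high-resolution isotropic protocol |
| `hemodynamic_delay_volumes` | 2 (7 s) | peak BOLD lag; the shift itself is standard, its magnitude is a configurable choice |
| `window_volumes` | 2, averaged | simplest label-preserving aggregation; single-volume patterns also supported |
| searchlight `radius_vox` | 1, chebyshev (27-voxel cube) | smallest local neighborhood that pools spatial context |
| `min_neighborhood` | 9 | suppresses scores from mask-edge stubs |
| `n_select` | 100 | information-map size; explicit, logged, not asserted as a fact about any real study |
| inner CV | stratified 5-fold | the inner loop runs once per voxel; leave-one-out would be ~10× slower for no calibration benefit |
| `C` | 1 | fixed; no hyperparameter search |
| `tol` | 1e-4 | solver contract, asserted by oracles |
| `p0` | `n_select / |ROI|` | uniform-selection null; required and logged |
| `alpha` | 0.001, uncorrected | the group threshold convention this analysis follows |
| effect size / noise | 1 / 1 | per-voxel d ≈ 2 after window averaging: strong but not trivial multivoxel signal |
| drift slope | 0.05 units/volume | visible linear drift for the detrend stage to remove |

Every run of `run_pipeline()` serializes the resolved configuration and a
log of all these values next to the outputs, with an md5 hash of the
configuration recorded in each decoding artifact, so any result can be
traced to the exact parameters that produced it.

## Numerical and degenerate-input choices

* Detrending fits intercept + slope per voxel over the *whole* run
  (including the rest gap) by closed-form least squares and subtracts the
  fit; residuals have zero mean and zero slope, and the operation is
  idempotent to 1e-10. Runs with fewer than two volumes are errors.
* Voxels are 0-based integer triples everywhere internally, ordered
  lexicographically by (x, y, z); this single ordering defines pattern
  matrix columns, score map order, and all tie-breaks. NIfTI affines are
  the only world-coordinate authority, and all windows are half-open
  `[start, start + len)`.
* Z-scoring guards zero-variance voxels (scale forced to 1); an all-zero
  sample contributes no dual constraint to the SVM.
* Ties: top-`n_select` selection breaks score ties by lexicographic voxel
  index; one-vs-one vote ties break by summed margin then lowest class id;
  `n_select` is clipped to the ROI size.
* Infeasible designs (no orderings without immediate repeats), overlapping
  ROI specs, masks exceeding the grid, trial windows overrunning the run,
  single-class training folds, and invalid probabilities are all explicit
  errors, not silent adjustments.

## Problem sizes used by the tests and acceptance script

The packaged simulations run at a 20³ grid with a ~224-voxel
hippocampus-analog ROI and two smaller ROIs, 10 subjects, and the full
51-trial design — the structure of the emulated study at a desk-friendly
grid. The chance-calibration suites use 20–25 full nested pipeline runs on
label permutations; unit tests use 12³ grids and 12-trial designs. These
sizes are the package's chosen testing conditions and are stated here so
results are interpretable; all of them are configuration, not constants.

## Known limitations

* The synthetic noise is white Gaussian; real BOLD noise is autocorrelated
  and structured, so real-data accuracies will differ from simulation.
* Only affine nearest-neighbor resampling is provided for group alignment;
  real multi-subject studies need nonlinear normalization upstream.
* The free-recall condition models label choice as near-uniform; real
  free-recall behavior has sequential dependencies that are out of scope.
* One-vs-one with C = 1 is the only classifier; there are no nonlinear
  kernels and no probability calibration, by design.
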