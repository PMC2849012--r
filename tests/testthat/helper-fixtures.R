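# Shared small fixtures, built in code.

# a solid cubical mask for geometry tests
solid_mask <- function(n = 5L, name = "CUBE") {
  vox <- as.matrix(expand.grid(x = 0:(n - 1L), y = 0:(n - 1L),
                               z = 0:(n - 1L)))
  roi_mask(vox, c(n, n, n), name = name)
}

# small design: 3 classes x 2 cued reps + 6 free = 12 trials
small_design <- function(seed = 1L) {
  generate_trial_design(design_config(
    n_classes = 3, cued_reps_per_class = 2, free_trials = 6,
    inter_trial_volumes = 4, rest_gap_volumes = 4, seed = seed))
}

# subject on a 12^3 grid with a single small ROI; quick to decode
small_subject <- function(seed = 1L, effect_size = 1, noise_sd = 1) {
  mask <- generate_roi_masks(
    c(12L, 12L, 12L),
    list(list(name = "HC", center = c(5.5, 5.5, 5.5), radii = c(3, 3, 3))))$HC
  design <- small_design(seed)
  sig <- signal_config(n_informative_clusters = 2, effect_size = effect_size,
                       noise_sd = noise_sd, seed = seed + 100L)
  sim <- synthesize_run(design, mask, sig)
  pats <- extract_trial_patterns(linear_detrend(sim$run),
                                 shift_onsets(design, 2, 2), mask, 2)
  list(mask = mask, design = design, truth = sim$truth, run = sim$run,
       patterns = pats)
}

# brute-force searchlight neighborhood by offset enumeration
oracle_neighborhood <- function(mask, center, radius, metric) {
  keep <- apply(mask$voxels, 1, function(v) {
    d <- abs(v - center)
    if (metric == "chebyshev") max(d) <= radius else sum(d^2) <= radius^2
  })
  mask$voxels[keep, , drop = FALSE]
}

# Jaccard index between two voxel sets given as m x 3 matrices
jaccard_voxels <- function(a, b) {
  ka <- paste(a[, 1], a[, 2], a[, 3])
  kb <- paste(b[, 1], b[, 2], b[, 3])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# chebyshev dilation of a voxel set, clipped to a mask
dilate_voxels <- function(vox, mask, radius = 1L) {
  offs <- as.matrix(expand.grid(-radius:radius, -radius:radius,
                                -radius:radius))
  grown <- unique(do.call(rbind, lapply(seq_len(nrow(vox)), function(i) {
    sweep(offs, 2, as.integer(vox[i, ]), `+`)
  })))
  keep <- paste(grown[, 1], grown[, 2], grown[, 3]) %in%
    paste(mask$voxels[, 1], mask$voxels[, 2], mask$voxels[, 3])
  grown[keep, , drop = FALSE]
}
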