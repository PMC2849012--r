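test_that("zero effect size yields pure drift + noise with all-zero patterns", {
  d <- small_design(1)
  mask <- solid_mask(6)
  sig <- signal_config(effect_size = 0, noise_sd = 1, drift_slope = 0.1,
                       seed = 2)
  sim <- synthesize_run(d, mask, sig)
  expect_true(all(sim$truth$class_patterns == 0))
  # with the implanted term zero, every voxel is baseline + drift + N(0,1)
  vmeans <- apply(sim$run$data, 4, mean)
  t_idx <- seq_along(vmeans) - 1L
  fit <- lm(vmeans ~ t_idx)
  expect_equal(unname(coef(fit)), c(100, 0.1), tolerance = 0.02)
})

test_that("near-noiseless single-window mean recovers the class pattern", {
  d <- small_design(2)
  mask <- solid_mask(6)
  sig <- signal_config(n_informative_clusters = 2, effect_size = 2,
                       noise_sd = 1e-6, drift_slope = 0,
                       hemodynamic_delay_volumes = 2,
                       pattern_window_volumes = 2, seed = 5)
  sim <- synthesize_run(d, mask, sig)
  info_lin <- episearch:::voxel_linear_index(sim$truth$informative_voxels,
                                             mask$grid_shape)
  # direct arithmetic oracle on trial 1's shifted window
  t0 <- d$onset_volume[1] + 2L
  win <- (sim$run$data[, , , t0 + 1L] + sim$run$data[, , , t0 + 2L]) / 2
  recovered <- win[info_lin] - sig$baseline
  expect_equal(recovered, sim$truth$class_patterns[d$label[1], ],
               tolerance = 1e-4)
})

test_that("class patterns are pairwise distinct sign patterns", {
  d <- small_design(3)
  sim <- synthesize_run(d, solid_mask(6),
                        signal_config(effect_size = 1.5, seed = 11))
  pat <- sim$truth$class_patterns
  expect_true(all(abs(pat) == 1.5))
  expect_equal(nrow(unique(pat)), 3L)
  expect_true(all(paste(sim$truth$informative_voxels[, 1],
                        sim$truth$informative_voxels[, 2],
                        sim$truth$informative_voxels[, 3]) %in%
                  paste(solid_mask(6)$voxels[, 1], solid_mask(6)$voxels[, 2],
                        solid_mask(6)$voxels[, 3])))
})

test_that("identical seeds give bit-identical runs; window overrun errors", {
  d <- small_design(4)
  mask <- solid_mask(5)
  sig <- signal_config(seed = 9)
  s1 <- synthesize_run(d, mask, sig)
  s2 <- synthesize_run(d, mask, sig)
  expect_identical(s1$run$data, s2$run$data)
  expect_identical(s1$truth, s2$truth)
  sig_bad <- signal_config(seed = 9, hemodynamic_delay_volumes = 50)
  expect_error(synthesize_run(d, mask, sig_bad), "overruns")
})

test_that("voxels outside the informative set carry no label information", {
  # permutation-free check: per-voxel F statistics of label on uninformative
  # voxels should match the null rate at a loose alpha
  d <- generate_trial_design(design_config(
    n_classes = 3, cued_reps_per_class = 7, free_trials = 15, seed = 21))
  mask <- solid_mask(7)
  sig <- signal_config(effect_size = 3, noise_sd = 1, seed = 22)
  sim <- synthesize_run(d, mask, sig)
  pats <- extract_trial_patterns(linear_detrend(sim$run),
                                 shift_onsets(d, 2, 2), mask, 2)
  info <- paste(sim$truth$informative_voxels[, 1],
                sim$truth$informative_voxels[, 2],
                sim$truth$informative_voxels[, 3])
  all_k <- paste(mask$voxels[, 1], mask$voxels[, 2], mask$voxels[, 3])
  outside <- which(!(all_k %in% info))
  pvals <- vapply(outside, function(j) {
    summary(aov(pats$matrix[, j] ~ factor(pats$labels)))[[1]][1, "Pr(>F)"]
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.12)  # ~5% expected, loose bound
  inside <- which(all_k %in% info)
  p_in <- vapply(inside, function(j) {
    summary(aov(pats$matrix[, j] ~ factor(pats$labels)))[[1]][1, "Pr(>F)"]
  }, numeric(1))
  # implanted voxels carry signal unless all three class signs coincide,
  # which happens for ~1/4 of voxels under random sign patterns
  expect_gt(mean(p_in < 0.05), 0.6)
})

test_that("cohorts share or individuate clusters as configured", {
  mask <- solid_mask(7)
  dcfg <- design_config(n_classes = 3, cued_reps_per_class = 1,
                        free_trials = 3)
  sig <- signal_config(n_informative_clusters = 2)
  shared <- generate_cohort(4, dcfg, mask, sig, cluster_sharing = 1,
                            master_seed = 5)
  truth_sets <- lapply(shared, function(s) s$truth$informative_voxels)
  for (i in 2:4) expect_identical(truth_sets[[i]], truth_sets[[1]])

  indep <- generate_cohort(4, dcfg, mask, sig, cluster_sharing = 0,
                           master_seed = 5)
  truth_indep <- lapply(indep, function(s) s$truth$informative_voxels)
  expect_false(identical(truth_indep[[1]], truth_indep[[2]]))

  expect_error(generate_cohort(0, dcfg, mask, sig), "n_subjects")
})

test_that("independent cohorts overlap at the chance rate", {
  # Monte-Carlo oracle: with independent single-voxel 'clusters' of radius 0,
  # two subjects share an informative voxel with probability ~ m/|ROI| per
  # draw; compare mean pairwise overlap against the hypergeometric mean.
  mask <- solid_mask(8)  # 512 voxels
  dcfg <- design_config(n_classes = 3, cued_reps_per_class = 1,
                        free_trials = 3)
  sig <- signal_config(n_informative_clusters = 12, cluster_radius_vox = 0)
  n_vox <- nrow(mask$voxels)
  overlaps <- unlist(lapply(1:30, function(ms) {
    coh <- generate_cohort(2, dcfg, mask, sig, cluster_sharing = 0,
                           master_seed = ms)
    a <- coh[[1]]$truth$informative_voxels
    b <- coh[[2]]$truth$informative_voxels
    length(intersect(paste(a[, 1], a[, 2], a[, 3]),
                     paste(b[, 1], b[, 2], b[, 3])))
  }))
  expected <- 12 * 12 / n_vox  # E[|A ∩ B|] for independent 12-subsets
  expect_equal(mean(overlaps), expected, tolerance = 0.5)
})
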