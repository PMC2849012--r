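#' Multivoxel signal configuration
#'
#' Parameters of the implanted class-specific signal and nuisance structure
#' used by [synthesize_run()]. The signal model is deliberately simple: each
#' memory class has a fixed spatial amplitude pattern (+/- `effect_size`)
#' over a small set of informative voxels, added as a boxcar over
#' `pattern_window_volumes` volumes starting `hemodynamic_delay_volumes`
#' after each trial onset, on top of a per-voxel baseline, a linear drift and
#' i.i.d. Gaussian noise. Because the decoding pipeline only ever consumes
#' window averages, a boxcar (rather than a convolved hemodynamic response)
#' keeps the arithmetic oracles in the test-suite exact.
#'
#' @param n_informative_clusters Number of informative clusters implanted in
#'   the ROI (default 3, one focus per memory-relevant subregion).
#' @param cluster_radius_vox Euclidean radius of each cluster in voxels
#'   (default 1: a 7-voxel ball, clipped to the ROI).
#' @param effect_size Per-voxel signal amplitude, in units of `noise_sd`
#'   (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param drift_slope Linear drift in signal units per volume (default 0.05).
#' @param hemodynamic_delay_volumes Onset-to-response lag in volumes
#'   (default 2, i.e. 7 s at TR = 3.5 s).
#' @param pattern_window_volumes Length of the boxcar signal window
#'   (default 2).
#' @param baseline Constant baseline intensity (default 100).
#' @param seed Integer seed.
#' @return A `signal_config` list.
#' @export
signal_config <- function(n_informative_clusters = 3, cluster_radius_vox = 1,
                          effect_size = 1, noise_sd = 1, drift_slope = 0.05,
                          hemodynamic_delay_volumes = 2,
                          pattern_window_volumes = 2,
                          baseline = 100, seed = 1L) {
  structure(list(
    n_informative_clusters = check_count(n_informative_clusters,
                                         "n_informative_clusters"),
    cluster_radius_vox = check_number(cluster_radius_vox,
                                      "cluster_radius_vox", min = 0),
    effect_size = check_number(effect_size, "effect_size", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict = TRUE),
    drift_slope = check_number(drift_slope, "drift_slope"),
    hemodynamic_delay_volumes = check_count(hemodynamic_delay_volumes,
                                            "hemodynamic_delay_volumes",
                                            min = 0L),
    pattern_window_volumes = check_count(pattern_window_volumes,
                                         "pattern_window_volumes"),
    baseline = check_number(baseline, "baseline"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "signal_config")
}

# Euclidean ball of given radius around each center, clipped to the mask.
cluster_voxels <- function(centers, radius, mask) {
  mk <- voxel_key(mask$voxels)
  sel <- logical(nrow(mask$voxels))
  for (i in seq_len(nrow(centers))) {
    d2 <- (mask$voxels[, 1] - centers[i, 1])^2 +
          (mask$voxels[, 2] - centers[i, 2])^2 +
          (mask$voxels[, 3] - centers[i, 3])^2
    sel <- sel | d2 <= radius^2 + 1e-12
  }
  mask$voxels[sel, , drop = FALSE]
}

# Random sign patterns (+/- effect_size), one row per class; orthogonal in
# expectation, re-drawn on the (measure-zero) event of duplicate rows.
draw_class_patterns <- function(n_classes, n_voxels, effect_size) {
  if (effect_size == 0) return(matrix(0, n_classes, n_voxels))
  repeat {
    pat <- matrix(sample(c(-1, 1), n_classes * n_voxels, replace = TRUE),
                  n_classes, n_voxels) * effect_size
    if (nrow(unique(pat)) == n_classes) return(pat)
  }
}

new_ground_truth <- function(informative_voxels, class_patterns) {
  structure(list(informative_voxels = informative_voxels,
                 class_patterns = class_patterns),
            class = "ground_truth")
}

# Draw cluster centers from the mask; `fixed_centers` (rows) are kept and
# only the remainder are sampled, which is how cohort-level sharing works.
draw_cluster_centers <- function(mask, n_clusters, fixed_centers = NULL) {
  n_fixed <- if (is.null(fixed_centers)) 0L else nrow(fixed_centers)
  n_new <- n_clusters - n_fixed
  stopifnot(n_new >= 0L)
  new_idx <- sample.int(nrow(mask$voxels), n_new)
  rbind(fixed_centers, mask$voxels[new_idx, , drop = FALSE])
}

#' Synthesize one subject's BOLD run
#'
#' Builds a 4D voxel time-series with the statistical structure the decoding
#' pipeline assumes: everywhere, `baseline + drift_slope * volume +
#' N(0, noise_sd)`; additionally, for every trial, the trial's class pattern
#' is added over the informative voxels in a window of
#' `pattern_window_volumes` volumes starting `hemodynamic_delay_volumes`
#' after the trial onset. Informative voxels are the union of
#' `n_informative_clusters` Euclidean balls centered at mask voxels (clipped
#' to the mask).
#'
#' @param design A `trial_design` (unshifted onsets).
#' @param mask An [roi_mask()].
#' @param sig A [signal_config()].
#' @param tr_s Repetition time in seconds (default 3.5).
#' @param cluster_centers Optional fixed cluster centers (m x 3, 0-based);
#'   used by [generate_cohort()] to share clusters across subjects. If fewer
#'   than `n_informative_clusters` rows, the remainder are drawn at random.
#' @return List with elements `run` (a `bold_run`) and `truth` (a
#'   `ground_truth` with `informative_voxels` and `class_patterns`).
#' @export
synthesize_run <- function(design, mask, sig = signal_config(), tr_s = 3.5,
                           cluster_centers = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(mask, "roi_mask"),
            inherits(sig, "signal_config"))
  n_vol <- attr(design, "n_volumes")
  n_classes <- attr(design, "n_classes")
  grid <- mask$grid_shape
  win_start <- design$onset_volume + sig$hemodynamic_delay_volumes
  if (any(win_start + sig$pattern_window_volumes > n_vol)) {
    abort("signal window overruns the run: increase n_volumes or reduce delay/window")
  }
  with_seed(sig$seed, {
    centers <- draw_cluster_centers(mask, sig$n_informative_clusters,
                                    cluster_centers)
    info_vox <- lex_sort_voxels(
      cluster_voxels(centers, sig$cluster_radius_vox, mask))
    patterns <- draw_class_patterns(n_classes, nrow(info_vox),
                                    sig$effect_size)
    data <- array(rnorm(prod(grid) * n_vol, sd = sig$noise_sd),
                  dim = c(grid, n_vol))
  })
  drift <- sig$baseline + sig$drift_slope * (seq_len(n_vol) - 1L)
  data <- data + rep(drift, each = prod(grid))
  info_lin <- voxel_linear_index(info_vox, grid)
  vol_stride <- prod(grid)
  for (i in seq_len(nrow(design))) {
    pat <- patterns[design$label[i], ]
    for (t in win_start[i] + seq_len(sig$pattern_window_volumes) - 1L) {
      idx <- info_lin + t * vol_stride
      data[idx] <- data[idx] + pat
    }
  }
  list(run = bold_run(data, tr_s = tr_s),
       truth = new_ground_truth(info_vox, patterns))
}

#' Generate a synthetic cohort
#'
#' Generates `n_subjects` independent subject datasets on a shared grid and
#' ROI geometry. Informative clusters are drawn from a common spatial prior:
#' a fraction `cluster_sharing` of each subject's clusters sit at
#' cohort-level shared centers (drawn once from `master_seed`), the rest at
#' subject-specific random centers — so the expected group overlap of
#' information maps is controllable from fully shared (`1`) to independent
#' (`0`). Per-subject seeds are `master_seed + subject` (design) and
#' `master_seed + 1000 + subject` (signal), so any subject can be
#' regenerated in isolation.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param design_cfg A [design_config()]; its seed field is overridden
#'   per subject.
#' @param mask An [roi_mask()] shared by the cohort.
#' @param sig A [signal_config()]; its seed field is overridden per subject.
#' @param cluster_sharing Fraction in `[0, 1]` of clusters shared across
#'   subjects (default 1).
#' @param master_seed Integer master seed.
#' @param tr_s Repetition time in seconds.
#' @return List of subjects; each has `subject` (id), `design`, `run`,
#'   `truth`.
#' @export
generate_cohort <- function(n_subjects = 10, design_cfg = design_config(),
                            mask, sig = signal_config(),
                            cluster_sharing = 1, master_seed = 1L,
                            tr_s = 3.5) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  stopifnot(cluster_sharing >= 0, cluster_sharing <= 1)
  master_seed <- check_count(master_seed, "master_seed",
                             min = -.Machine$integer.max)
  n_shared <- round(cluster_sharing * sig$n_informative_clusters)
  shared_centers <- if (n_shared > 0L) {
    with_seed(master_seed, {
      idx <- sample.int(nrow(mask$voxels), n_shared)
      mask$voxels[idx, , drop = FALSE]
    })
  }
  lapply(seq_len(n_subjects), function(s) {
    dcfg <- design_cfg
    dcfg$seed <- master_seed + s
    scfg <- sig
    scfg$seed <- master_seed + 1000L + s
    design <- generate_trial_design(dcfg)
    sim <- synthesize_run(design, mask, scfg, tr_s = tr_s,
                          cluster_centers = shared_centers)
    list(subject = s, design = design, run = sim$run, truth = sim$truth)
  })
}
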