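#' 4D BOLD run container
#'
#' A thin wrapper around a 4D array `(x, y, z, volume)` with its repetition
#' time. Values must be finite and the run must hold at least 2 volumes.
#'
#' @param data 4D numeric array.
#' @param tr_s Repetition time in seconds (default 3.5).
#' @return A `bold_run`.
#' @export
bold_run <- function(data, tr_s = 3.5) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[4] < 2L) abort("a BOLD run needs at least 2 volumes")
  if (!all(is.finite(data))) abort("BOLD run contains non-finite values")
  structure(list(data = data,
                 tr_s = check_number(tr_s, "tr_s", min = 0, strict = TRUE),
                 grid_shape = dim(data)[1:3]),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run: %s grid, %d volumes, TR %.2f s>\n",
              paste(x$grid_shape, collapse = "x"), dim(x$data)[4], x$tr_s))
  invisible(x)
}

#' Linear detrend of a BOLD run
#'
#' Fits a first-order polynomial (intercept + slope over volume index) to
#' every voxel's full time-series by ordinary least squares and subtracts
#' it. After detrending each voxel series has zero mean and zero
#' least-squares slope; the operation is idempotent. The fit always spans
#' the whole run, including any rest gap between conditions.
#'
#' @param run A [bold_run()].
#' @return The detrended `bold_run`.
#' @export
linear_detrend <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  n_vol <- d[4]
  y <- matrix(run$data, nrow = prod(d[1:3]), ncol = n_vol)  # voxels x time
  t_c <- seq_len(n_vol) - mean(seq_len(n_vol))              # centered time
  slope <- (y %*% t_c) / sum(t_c^2)
  fitted <- rowMeans(y) + slope %*% rbind(t_c)
  run$data <- array(y - fitted, dim = d)
  run
}

#' Pattern set: one feature vector per trial
#'
#' Trials-by-voxels matrix with per-trial labels and conditions, tied to the
#' ROI mask whose lexicographically ordered voxels define the column order.
#'
#' @param matrix Trials x voxels numeric matrix.
#' @param labels Integer class labels, one per trial.
#' @param condition Character `"cued"`/`"free"`, one per trial.
#' @param voxel_index m x 3 matrix of 0-based voxel indices (column order).
#' @param mask_name Name of the source ROI.
#' @return A `pattern_set`.
#' @export
pattern_set <- function(matrix, labels, condition, voxel_index,
                        mask_name = "ROI") {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(labels),
            nrow(matrix) == length(condition),
            ncol(matrix) == nrow(voxel_index))
  structure(list(matrix = matrix,
                 labels = as.integer(labels),
                 condition = as.character(condition),
                 voxel_index = voxel_index,
                 mask_name = as.character(mask_name)),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set '%s': %d trials x %d voxels, %d classes>\n",
              x$mask_name, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$labels))))
  invisible(x)
}

#' @describeIn pattern_set Tidy view: one row per trial, `label` and
#'   `condition` first, then one column per voxel named `v<x>_<y>_<z>`.
#' @param x A `pattern_set`.
#' @param ... Unused.
#' @export
as_tibble.pattern_set <- function(x, ...) {
  m <- x$matrix
  colnames(m) <- sprintf("v%d_%d_%d", x$voxel_index[, 1], x$voxel_index[, 2],
                         x$voxel_index[, 3])
  dplyr::bind_cols(
    tibble(trial = seq_len(nrow(m)), label = x$labels,
           condition = x$condition),
    as_tibble(m)
  )
}

#' Extract one pattern vector per trial
#'
#' For each trial, averages the `window_volumes` volumes starting at the
#' trial's (already shifted) onset and restricts the result to the mask
#' voxels, in the mask's lexicographic voxel order.
#'
#' @param run A [bold_run()] (typically detrended).
#' @param design A shifted `trial_design` (see [shift_onsets()]).
#' @param mask An [roi_mask()] on the run's grid.
#' @param window_volumes Number of volumes to average (default 2).
#' @return A [pattern_set()].
#' @export
extract_trial_patterns <- function(run, design, mask, window_volumes = 2L) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "trial_design"),
            inherits(mask, "roi_mask"))
  window_volumes <- check_count(window_volumes, "window_volumes")
  if (!identical(unname(run$grid_shape), unname(mask$grid_shape))) {
    abort("run and mask are on different grids")
  }
  if (nrow(mask$voxels) == 0L) abort("empty mask")
  n_vol <- dim(run$data)[4]
  if (any(design$onset_volume + window_volumes > n_vol)) {
    abort("pattern window overruns the run for at least one trial")
  }
  vox_lin <- voxel_linear_index(mask$voxels, mask$grid_shape)
  vol_stride <- prod(mask$grid_shape)
  mat <- t(vapply(seq_len(nrow(design)), function(i) {
    vols <- design$onset_volume[i] + seq_len(window_volumes) - 1L
    idx <- outer(vox_lin, vols * vol_stride, `+`)
    rowMeans(matrix(run$data[idx], nrow = length(vox_lin)))
  }, numeric(length(vox_lin))))
  pattern_set(mat, design$label, design$condition, mask$voxels,
              mask_name = mask$name)
}
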