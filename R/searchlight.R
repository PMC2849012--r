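#' Searchlight specification
#'
#' Defines the local neighborhood scored around each ROI voxel: all mask
#' voxels within `radius_vox` of the center under the chosen metric
#' (`"chebyshev"` gives a cube, `"euclidean"` a ball), center included.
#' Neighborhoods that end up smaller than `min_neighborhood` (at mask
#' borders) are not scored and receive score 0.
#'
#' @param radius_vox Non-negative integer radius (default 1: the 27-voxel
#'   chebyshev cube).
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @param min_neighborhood Minimum neighborhood size to score (default 9).
#' @return A `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_vox = 1L, metric = c("chebyshev",
                                                         "euclidean"),
                             min_neighborhood = 9L) {
  structure(list(radius_vox = check_count(radius_vox, "radius_vox", min = 0L),
                 metric = match.arg(metric),
                 min_neighborhood = check_count(min_neighborhood,
                                                "min_neighborhood")),
            class = "searchlight_spec")
}

searchlight_offsets <- function(spec) {
  r <- spec$radius_vox
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  if (spec$metric == "euclidean") {
    g <- g[rowSums(g^2) <= r^2 + 1e-12, , drop = FALSE]
  }
  g
}

#' Searchlight neighborhood of one voxel
#'
#' All mask voxels within the spec's radius of `center` (center included),
#' in lexicographic (x, y, z) order.
#'
#' @param mask An [roi_mask()].
#' @param center Length-3 0-based voxel index; must belong to the mask.
#' @param spec A [searchlight_spec()].
#' @return m x 3 integer matrix of 0-based voxel indices.
#' @export
neighborhood <- function(mask, center, spec = searchlight_spec()) {
  stopifnot(inherits(mask, "roi_mask"), length(center) == 3L)
  center <- as.integer(center)
  if (!any(mask$voxels[, 1] == center[1] & mask$voxels[, 2] == center[2] &
           mask$voxels[, 3] == center[3])) {
    abort("searchlight center is not a mask voxel")
  }
  cand <- sweep(searchlight_offsets(spec), 2, center, `+`)
  keep <- cand[cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
               cand[, 1] < mask$grid_shape[1] &
               cand[, 2] < mask$grid_shape[2] &
               cand[, 3] < mask$grid_shape[3], , drop = FALSE]
  in_mask <- voxel_key(keep) %in% voxel_key(mask$voxels)
  lex_sort_voxels(keep[in_mask, , drop = FALSE])
}

# For every mask voxel, the columns (1-based, in mask voxel order) of its
# neighborhood. Computed via a linear-index lookup table, O(V * |offsets|).
all_neighborhood_columns <- function(mask, spec) {
  grid <- mask$grid_shape
  lut <- integer(prod(grid))
  vox_lin <- voxel_linear_index(mask$voxels, grid)
  lut[vox_lin] <- seq_len(nrow(mask$voxels))
  offs <- searchlight_offsets(spec)
  lapply(seq_len(nrow(mask$voxels)), function(v) {
    cand <- sweep(offs, 2, mask$voxels[v, ], `+`)
    ok <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
          cand[, 1] < grid[1] & cand[, 2] < grid[2] & cand[, 3] < grid[3]
    cols <- lut[voxel_linear_index(cand[ok, , drop = FALSE], grid)]
    sort(cols[cols > 0L])  # mask order is lexicographic, so sorted = lex
  })
}

# Deterministic stratified fold assignment: within each label, trials (in
# index order) are dealt to folds 1..k cyclically.
stratified_folds <- function(labels, k) {
  k <- check_count(k, "inner_folds", min = 2L)
  if (length(labels) < k) abort("fewer trials than folds")
  fold <- integer(length(labels))
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Score every ROI voxel by local decodability
#'
#' For each ROI voxel, restricts the pattern matrix to the voxel's
#' searchlight neighborhood and estimates how well the memory classes can be
#' decoded from that local pattern: a stratified `inner_folds`-fold
#' cross-validated one-vs-one linear SVM (see [train_multiclass()]), with
#' per-voxel z-scoring computed from each training fold only. The mean
#' cross-validated accuracy is the voxel's score. Neighborhoods smaller than
#' the spec's `min_neighborhood` score 0.
#'
#' @param patterns A [pattern_set()] extracted from `mask`.
#' @param mask The source [roi_mask()].
#' @param spec A [searchlight_spec()].
#' @param inner_folds Number of stratified folds (default 5).
#' @param cfg A [classifier_config()].
#' @param trials Optional integer subset of trials to score on (used by the
#'   nested cross-validation to confine scoring to training trials).
#' @param .nbhd Precomputed neighborhood columns (internal cache used by
#'   [cross_validate_decoding()] to avoid rebuilding them per fold).
#' @return A `score_map`: per-ROI-voxel scores in `[0, 1]` aligned with the
#'   mask's voxel order.
#' @export
score_searchlights <- function(patterns, mask, spec = searchlight_spec(),
                               inner_folds = 5L, cfg = classifier_config(),
                               trials = NULL, .nbhd = NULL) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(mask, "roi_mask"))
  if (!identical(patterns$voxel_index, mask$voxels)) {
    abort("pattern set does not match this mask's voxels")
  }
  trials <- trials %||% seq_len(nrow(patterns$matrix))
  labels <- patterns$labels[trials]
  if (length(trials) < inner_folds) abort("fewer trials than inner folds")
  fold <- stratified_folds(labels, inner_folds)
  nbhd <- .nbhd %||% all_neighborhood_columns(mask, spec)
  scores <- cpp_searchlight_scores(
    patterns$matrix[trials, , drop = FALSE], as.integer(labels), nbhd,
    as.integer(fold), cfg$C, cfg$tol, cfg$max_iter, TRUE,
    spec$min_neighborhood)
  structure(list(scores = as.numeric(scores), voxels = mask$voxels,
                 mask_name = mask$name, grid_shape = mask$grid_shape,
                 spec = spec, n_inner_folds = as.integer(inner_folds)),
            class = "score_map")
}

#' Dense array form of a score map
#'
#' @param x A `score_map`.
#' @return 3D numeric array with searchlight scores at ROI voxels and 0
#'   elsewhere (suitable for [write_volume()]).
#' @export
score_map_to_array <- function(x) {
  stopifnot(inherits(x, "score_map"))
  arr <- array(0, dim = x$grid_shape)
  arr[voxel_linear_index(x$voxels, x$grid_shape)] <- x$scores
  arr
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map '%s': %d voxels, scores %.2f-%.2f>\n",
              x$mask_name, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Select the most informative voxels
#'
#' The subject's information map: the `n_select` highest-scoring ROI voxels.
#' Ties are broken by lexicographic voxel index, so selection is
#' deterministic; `n_select` is clipped to the ROI size.
#'
#' @param scores A `score_map` from [score_searchlights()].
#' @param n_select Number of voxels to select (default 100).
#' @param subject Optional subject id recorded in the map.
#' @return An `information_map` with the selected 0-based voxel indices.
#' @export
build_information_map <- function(scores, n_select = 100L, subject = NA) {
  stopifnot(inherits(scores, "score_map"))
  n_select <- check_count(n_select, "n_select")
  n <- min(n_select, length(scores$scores))
  # mask voxels are lexicographic; stable order() yields the tie rule
  top <- order(-scores$scores)[seq_len(n)]
  structure(list(selected = scores$voxels[sort(top), , drop = FALSE],
                 n_select = as.integer(n),
                 roi_name = scores$mask_name,
                 grid_shape = scores$grid_shape,
                 subject = subject),
            class = "information_map")
}

#' @export
print.information_map <- function(x, ...) {
  cat(sprintf("<information_map '%s'%s: %d voxels>\n", x$roi_name,
              if (is.na(x$subject)) "" else sprintf(" subject %s", x$subject),
              nrow(x$selected)))
  invisible(x)
}

#' Ranking table of searchlight scores
#'
#' @param x A `score_map`.
#' @param ... Unused.
#' @return Tibble with voxel indices and scores, best first (ties in
#'   lexicographic voxel order).
#' @export
tidy.score_map <- function(x, ...) {
  vox <- x$voxels
  sc <- x$scores
  tibble(x = vox[, 1], y = vox[, 2], z = vox[, 3], score = sc) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
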