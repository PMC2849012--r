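#' Group frequency heat map
#'
#' Adds subject information maps together on the common grid: the value at a
#' voxel is the number of subjects whose information map contains that
#' voxel, so with 10 subjects the maximum attainable frequency is 10.
#' Synthetic cohorts share a grid by construction; externally supplied maps
#' on a different grid must first be brought onto the common grid with
#' [resample_information_map()].
#'
#' @param maps Non-empty list of `information_map` objects on one grid.
#' @param grid_shape Common grid extents; defaults to the first map's grid.
#' @return A `heat_map`: integer 3D array plus `n_subjects`.
#' @export
aggregate_heat_map <- function(maps, grid_shape = NULL) {
  if (length(maps) == 0L) abort("need at least one information map")
  stopifnot(all(vapply(maps, inherits, logical(1), "information_map")))
  grid_shape <- grid_shape %||% maps[[1]]$grid_shape
  for (m in maps) {
    if (!identical(unname(as.integer(m$grid_shape)),
                   unname(as.integer(grid_shape)))) {
      abort(paste("information maps are on different grids;",
                  "resample with resample_information_map() first"))
    }
  }
  counts <- array(0L, dim = grid_shape)
  for (m in maps) {
    idx <- voxel_linear_index(m$selected, grid_shape)
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(counts = counts, n_subjects = length(maps),
                 grid_shape = as.integer(grid_shape),
                 roi_name = maps[[1]]$roi_name),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map '%s': %d subjects, max frequency %d>\n",
              x$roi_name, x$n_subjects, max(x$counts)))
  invisible(x)
}

# Exact inclusive upper binomial tail P(X >= k), X ~ Binomial(n, p0),
# by term-by-term summation of the mass function.
binom_upper_tail <- function(k, n, p0) {
  vapply(k, function(ki) {
    if (ki <= 0) return(1)
    sum(dbinom(ki:n, n, p0))
  }, numeric(1))
}

#' Voxelwise binomial p-values for a heat map
#'
#' Compares the frequency count at each voxel against the binomial
#' distribution: with `n` subjects and a null per-subject selection
#' probability `p0`, the p-value at a voxel with frequency `k` is the
#' inclusive upper tail `P(X >= k)` for `X ~ Binomial(n, p0)`, computed by
#' exact summation of the mass function. The inclusive upper tail tests
#' over-representation of the voxel across subjects.
#'
#' A natural null probability is uniform selection within the ROI,
#' `p0 = n_select / |ROI|`; `p0` is a required, logged parameter because the
#' significance of any given frequency count depends on it.
#'
#' @param heat A `heat_map`.
#' @param p0 Null per-subject selection probability, strictly in (0, 1).
#' @return A `p_map`: 3D array of p-values in (0, 1] plus `p0` and
#'   `n_subjects`.
#' @export
binomial_voxel_pvalues <- function(heat, p0) {
  stopifnot(inherits(heat, "heat_map"))
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    abort("`p0` must be a single probability strictly between 0 and 1")
  }
  n <- heat$n_subjects
  tail_by_k <- binom_upper_tail(0:n, n, p0)  # lookup over the k range
  p <- array(tail_by_k[heat$counts + 1L], dim = heat$grid_shape)
  structure(list(p = p, p0 = p0, n_subjects = n,
                 grid_shape = heat$grid_shape, roi_name = heat$roi_name),
            class = "p_map")
}

#' @export
print.p_map <- function(x, ...) {
  cat(sprintf("<p_map '%s': n = %d, p0 = %.4g, min p = %.3g>\n",
              x$roi_name, x$n_subjects, x$p0, min(x$p)))
  invisible(x)
}

#' Threshold a p-value map
#'
#' Returns the voxels whose binomial p-value is strictly below `alpha`.
#' Uncorrected by default, matching the reported group analysis; an optional
#' Bonferroni flag divides `alpha` by the number of tested voxels.
#'
#' @param pmap A `p_map`.
#' @param alpha Significance level in (0, 1).
#' @param bonferroni If `TRUE`, use `alpha / n_tests`.
#' @param n_tests Number of voxels tested (for Bonferroni); defaults to the
#'   number of voxels any subject selected (p < 1).
#' @return Integer matrix (m x 3) of significant 0-based voxel indices in
#'   lexicographic order, with the effective threshold as attribute
#'   `alpha_effective`.
#' @export
threshold_map <- function(pmap, alpha = 0.001, bonferroni = FALSE,
                          n_tests = NULL) {
  stopifnot(inherits(pmap, "p_map"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value strictly between 0 and 1")
  }
  eff <- alpha
  if (bonferroni) {
    n_tests <- n_tests %||% sum(pmap$p < 1)
    if (n_tests < 1L) n_tests <- 1L
    eff <- alpha / n_tests
  }
  idx <- which(pmap$p < eff)
  vox <- if (length(idx)) {
    lex_sort_voxels(arrayInd(idx, pmap$grid_shape) - 1L)
  } else {
    matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  }
  structure(vox, alpha_effective = eff)
}

#' Resample an information map onto a target grid
#'
#' Nearest-neighbor affine resampling for externally supplied maps: each
#' selected voxel is mapped through its source affine to world coordinates,
#' then through the inverse target affine to target voxel indices, which are
#' rounded and clipped-checked. Synthetic cohorts never need this; it is the
#' alignment contract for maps from real, separately gridded subjects.
#' Nonlinear stereotactic normalization is out of scope.
#'
#' @param map An `information_map`.
#' @param src_affine,dst_affine 4x4 voxel-to-world affine matrices.
#' @param dst_grid Target grid extents.
#' @return An `information_map` on the target grid (duplicate hits merged).
#' @export
resample_information_map <- function(map, src_affine, dst_affine, dst_grid) {
  stopifnot(inherits(map, "information_map"),
            identical(dim(src_affine), c(4L, 4L)),
            identical(dim(dst_affine), c(4L, 4L)))
  vox_h <- cbind(map$selected, 1)  # homogeneous 0-based voxel coords
  world <- vox_h %*% t(src_affine)
  dst <- world %*% t(solve(dst_affine))
  dst_vox <- round(dst[, 1:3, drop = FALSE])
  if (any(dst_vox < 0 | dst_vox >= matrix(dst_grid, nrow(dst_vox), 3,
                                          byrow = TRUE))) {
    abort("resampled voxels fall outside the target grid")
  }
  dst_vox <- unique(lex_sort_voxels(dst_vox))
  structure(list(selected = dst_vox, n_select = nrow(dst_vox),
                 roi_name = map$roi_name,
                 grid_shape = as.integer(dst_grid), subject = map$subject),
            class = "information_map")
}
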