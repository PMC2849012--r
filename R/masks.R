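#' ROI mask on a voxel grid
#'
#' A region of interest as an explicit set of 0-based integer voxel indices
#' on a 3D grid, stored in lexicographic (x, y, z) order. This ordering is
#' the package-wide voxel ordering: pattern matrices, score maps and
#' information maps all index voxels the same way.
#'
#' @param voxels Integer matrix (m x 3) of 0-based (x, y, z) indices.
#' @param grid_shape Integer length-3 grid extents.
#' @param voxel_size_mm Isotropic voxel size in mm (default 1.5).
#' @param name ROI name, e.g. `"HC"`, `"EC"`, `"PHG"`.
#' @return An `roi_mask`.
#' @export
roi_mask <- function(voxels, grid_shape, voxel_size_mm = 1.5, name = "ROI") {
  grid_shape <- vapply(grid_shape, check_count, integer(1), name = "grid_shape")
  stopifnot(length(grid_shape) == 3L)
  voxels <- lex_sort_voxels(voxels)
  if (anyDuplicated(voxel_key(voxels))) abort("duplicate voxels in mask")
  stopifnot_voxels_in_grid(voxels, grid_shape, what = sprintf("mask '%s'", name))
  structure(list(voxels = voxels,
                 grid_shape = grid_shape,
                 voxel_size_mm = check_number(voxel_size_mm, "voxel_size_mm",
                                              min = 0, strict = TRUE),
                 name = as.character(name)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask '%s': %d voxels on %s grid, %.2g mm>\n", x$name,
              nrow(x$voxels), paste(x$grid_shape, collapse = "x"),
              x$voxel_size_mm))
  invisible(x)
}

# voxels of the discrete ellipsoid sum(((v - center)/radii)^2) <= 1
ellipsoid_voxels <- function(center, radii, grid_shape) {
  if (any(center - radii < -0.5) || any(center + radii > grid_shape - 0.5)) {
    abort("ROI spec exceeds the grid")
  }
  lo <- pmax(0L, floor(center - radii))
  hi <- pmin(grid_shape - 1L, ceiling(center + radii))
  g <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  d2 <- ((g[, 1] - center[1]) / radii[1])^2 +
        ((g[, 2] - center[2]) / radii[2])^2 +
        ((g[, 3] - center[3]) / radii[3])^2
  lex_sort_voxels(g[d2 <= 1 + 1e-12, , drop = FALSE])
}

#' Generate disjoint ellipsoidal ROI masks
#'
#' Builds one mask per spec as a discrete ellipsoid: the voxels whose
#' centers satisfy `sum(((v - center) / radii)^2) <= 1`. Masks must be
#' pairwise disjoint; overlap is an error. Deterministic.
#'
#' @param grid_shape Length-3 grid extents.
#' @param specs List of specs, each a list with `name`, `center` (length-3,
#'   0-based, may be fractional) and `radii` (length-3, in voxels). Defaults
#'   to [default_roi_specs()] analogs of hippocampus (HC), entorhinal cortex
#'   (EC) and parahippocampal gyrus (PHG).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Named list of [roi_mask()] objects.
#' @examples
#' masks <- generate_roi_masks(c(20, 20, 20))
#' vapply(masks, function(m) nrow(m$voxels), integer(1))
#' @export
generate_roi_masks <- function(grid_shape, specs = default_roi_specs(grid_shape),
                               voxel_size_mm = 1.5) {
  grid_shape <- vapply(grid_shape, check_count, integer(1), name = "grid_shape")
  masks <- lapply(specs, function(s) {
    stopifnot(is.list(s), length(s$center) == 3L, length(s$radii) == 3L)
    vox <- ellipsoid_voxels(as.numeric(s$center), as.numeric(s$radii),
                            grid_shape)
    if (nrow(vox) == 0L) {
      abort(sprintf("ROI spec '%s' produces an empty mask", s$name))
    }
    roi_mask(vox, grid_shape, voxel_size_mm = voxel_size_mm, name = s$name)
  })
  names(masks) <- vapply(specs, function(s) s$name, character(1))
  keys <- unlist(lapply(masks, function(m) voxel_key(m$voxels)))
  if (anyDuplicated(keys)) abort("ROI specs overlap: masks must be disjoint")
  masks
}

#' Default medial-temporal-lobe ROI layout
#'
#' Three disjoint ellipsoids sized relative to the grid, named after the
#' regions they stand in for: a larger HC analog and two smaller EC and PHG
#' analogs. On the default 20^3 grid this yields roughly 250, 60 and 60
#' voxels respectively.
#'
#' @param grid_shape Length-3 grid extents (each >= 16).
#' @return List of ROI specs for [generate_roi_masks()].
#' @export
default_roi_specs <- function(grid_shape = c(20L, 20L, 20L)) {
  g <- as.numeric(grid_shape)
  if (any(g < 16)) abort("default ROI layout needs a grid of at least 16^3")
  mid <- (g - 1) / 2
  list(
    list(name = "HC",  center = c(0.33 * g[1], mid[2], mid[3]),
         radii = c(0.24 * g[1], 0.17 * g[2], 0.17 * g[3])),
    list(name = "EC",  center = c(0.78 * g[1], 0.30 * g[2], mid[3]),
         radii = c(0.12 * g[1], 0.12 * g[2], 0.12 * g[3])),
    list(name = "PHG", center = c(0.78 * g[1], 0.70 * g[2], mid[3]),
         radii = c(0.12 * g[1], 0.12 * g[2], 0.12 * g[3]))
  )
}

# 0/1 integer array representation of a mask
mask_to_array <- function(mask) {
  arr <- array(0L, dim = mask$grid_shape)
  arr[voxel_linear_index(mask$voxels, mask$grid_shape)] <- 1L
  arr
}

# inverse of mask_to_array
array_to_mask <- function(arr, voxel_size_mm = 1.5, name = "ROI") {
  idx <- which(arr != 0)
  vox <- arrayInd(idx, dim(arr)) - 1L
  roi_mask(vox, dim(arr), voxel_size_mm = voxel_size_mm, name = name)
}
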