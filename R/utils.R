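# internal helpers

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d (got %s)",
                  name, min, deparse(x)))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- length(x) == 1L && is.finite(x) && (if (strict) x > min else x >= min)
  if (!ok) abort(sprintf("`%s` must be a single finite number %s %s",
                         name, if (strict) ">" else ">=", format(min)))
  as.numeric(x)
}

# Sort rows of an m x 3 voxel index matrix lexicographically by (x, y, z).
lex_sort_voxels <- function(vox) {
  vox <- matrix(as.integer(vox), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
}

# 0-based (x, y, z) rows -> 1-based linear indices into an array of dim grid.
voxel_linear_index <- function(vox, grid) {
  1L + vox[, 1] + grid[1] * (vox[, 2] + grid[2] * vox[, 3])
}

stopifnot_voxels_in_grid <- function(vox, grid, what = "voxel") {
  if (nrow(vox) == 0L) abort(sprintf("%s set is empty", what))
  bad <- vox < 0L | vox >= matrix(grid, nrow(vox), 3, byrow = TRUE)
  if (any(bad)) abort(sprintf("%s indices fall outside the grid", what))
  invisible(vox)
}

# key for set operations on voxel rows
voxel_key <- function(vox) paste(vox[, 1], vox[, 2], vox[, 3], sep = ",")
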