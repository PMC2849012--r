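#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (3D or 4D array), `affine` (4x4 voxel-to-world
#'   matrix) and `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    abort(sprintf("failed to parse NIfTI '%s': %s", path,
                                  conditionMessage(e)))
                  })
  aff <- structure(RNifti::xform(img), class = NULL)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = aff,
       voxel_size_mm = unname(sqrt(sum(aff[1:3, 1]^2))))
}

#' Write a NIfTI volume
#'
#' Masks and heat maps are written as integer volumes, everything else as
#' float32; shape, values (to float32 precision) and affine round-trip
#' through [read_volume()].
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size used to build a diagonal affine
#'   when none is given.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @param integer Write as integer datatype (for 0/1 masks and counts).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size_mm = 1.5, affine = NULL,
                         integer = FALSE) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
  }
  if (integer) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (integer) "int32" else "float")
  invisible(path)
}

#' Write / read a trial design as TSV
#'
#' Columns `onset_volume` (0-based), `condition`, `label`; run length and
#' class count travel in `# n_volumes=` / `# n_classes=` header comments.
#'
#' @param design A `trial_design`.
#' @param path TSV path.
#' @return `path` (write) or a `trial_design` (read), invisibly for write.
#' @export
write_design_tsv <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  header <- c(sprintf("# n_volumes=%d", attr(design, "n_volumes")),
              sprintf("# n_classes=%d", attr(design, "n_classes")))
  writeLines(header, path)
  readr::write_tsv(as_tibble(as.data.frame(design)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  get_field <- function(name) {
    m <- grep(sprintf("^# %s=", name), hdr, value = TRUE)
    if (length(m) != 1L) abort(sprintf("design TSV lacks '# %s=' header", name))
    as.integer(sub(".*=", "", m))
  }
  trials <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  trials <- tibble(onset_volume = as.integer(trials$onset_volume),
                   condition = as.character(trials$condition),
                   label = as.integer(trials$label))
  new_trial_design(trials, n_volumes = get_field("n_volumes"),
                   n_classes = get_field("n_classes"))
}

#' Write a pattern set as TSV
#'
#' One row per trial; `trial`, `label` and `condition` columns first, then
#' one column per voxel (named `v<x>_<y>_<z>`), for inspection outside R.
#'
#' @param patterns A [pattern_set()].
#' @param path TSV path.
#' @export
write_patterns_tsv <- function(patterns, path) {
  readr::write_tsv(as_tibble(patterns), path)
  invisible(path)
}

# write an information map / mask as a 0/1 volume
info_map_to_array <- function(map) {
  arr <- array(0L, dim = map$grid_shape)
  arr[voxel_linear_index(map$selected, map$grid_shape)] <- 1L
  arr
}
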