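#' @importFrom rlang .data
NULL

#' Tidy a decoding result
#'
#' One row per trial: fold, condition, true and predicted labels.
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.decoding_result <- function(x, ...) x$trials

#' One-row summary of a decoding result
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @return Tibble with `roi`, `accuracy`, `n_trials`, `n_classes`,
#'   `chance`, `n_select`, `selection`, `condition`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(roi = x$roi_name, accuracy = x$accuracy, n_trials = nrow(x$trials),
         n_classes = length(x$classes), chance = 1 / length(x$classes),
         n_select = x$n_select, selection = x$selection,
         condition = x$condition)
}

#' Tidy a permutation test
#'
#' @param x A `permutation_test`.
#' @param ... Unused.
#' @return Tibble with one row per permutation (`null_accuracy`).
#' @export
tidy.permutation_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null), null_accuracy = x$null)
}

#' @rdname tidy.permutation_test
#' @export
glance.permutation_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null),
         null_sd = stats::sd(x$null), p_value = x$p_value,
         n_perm = x$n_perm)
}

#' Tidy a heat map
#'
#' @param x A `heat_map`.
#' @param ... Unused.
#' @return Tibble of voxels with non-zero frequency.
#' @export
tidy.heat_map <- function(x, ...) {
  idx <- which(x$counts > 0L)
  vox <- arrayInd(idx, x$grid_shape) - 1L
  freq <- x$counts[idx]
  tibble(x = vox[, 1], y = vox[, 2], z = vox[, 3], frequency = freq) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$x, .data$y, .data$z)
}

# shared slice plotting over axial (z) sections
slice_tibble <- function(arr, grid, slices) {
  purrr::map_dfr(slices, function(z) {
    m <- arr[, , z + 1L]
    tibble(x = rep(0:(grid[1] - 1L), grid[2]),
           y = rep(0:(grid[2] - 1L), each = grid[1]),
           z = z, value = as.vector(m))
  })
}

mid_slices <- function(map_voxels, n = 3L) {
  zs <- sort(unique(map_voxels[, 3]))
  zs[unique(pmax(1L, round(seq(1, length(zs), length.out = n))))]
}

#' Plot searchlight scores on axial slices
#'
#' @param object A `score_map`.
#' @param slices 0-based z slices to show; defaults to three slices through
#'   the ROI.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.score_map <- function(object, slices = NULL, ...) {
  slices <- slices %||% mid_slices(object$voxels)
  arr <- array(NA_real_, dim = object$grid_shape)
  arr[voxel_linear_index(object$voxels, object$grid_shape)] <- object$scores
  df <- dplyr::filter(slice_tibble(arr, object$grid_shape, slices),
                      !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "score", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Searchlight scores, %s", object$mask_name))
}

#' Plot a group frequency heat map on axial slices
#'
#' @param object A `heat_map`.
#' @param slices 0-based z slices; defaults to the three busiest sections.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.heat_map <- function(object, slices = NULL, ...) {
  if (is.null(slices)) {
    per_z <- apply(object$counts, 3, sum)
    slices <- order(-per_z)[seq_len(min(3L, sum(per_z > 0)))] - 1L
  }
  df <- dplyr::filter(slice_tibble(object$counts, object$grid_shape, slices),
                      .data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "frequency", option = "inferno",
                                  limits = c(0, object$n_subjects)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Group frequency heat map, %s (n = %d)",
                                  object$roi_name, object$n_subjects))
}

#' Plot the confusion matrix of a decoding result
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_viridis_c(name = "trials") +
    ggplot2::labs(title = sprintf("%s: accuracy %.2f", object$roi_name,
                                  object$accuracy))
}

#' Plot a permutation null distribution
#'
#' @param object A `permutation_test`.
#' @param ... Unused.
#' @return A ggplot with the observed accuracy marked.
#' @export
autoplot.permutation_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(x = "null accuracy", y = "permutations",
                  title = sprintf("Permutation test: p = %.4f",
                                  object$p_value))
}
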