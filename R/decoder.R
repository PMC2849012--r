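#' Classifier configuration
#'
#' The decoder is a linear soft-margin support vector machine with the
#' regularization hyperparameter fixed at `C = 1` (no hyperparameter
#' search), extended to more than two classes by one-vs-one pairwise voting.
#'
#' @param C Soft-margin cost (> 0, default 1).
#' @param tol Solver tolerance on the projected gradient (default 1e-4).
#' @param max_iter Maximum coordinate-descent sweeps (default 1000).
#' @param multiclass Multiclass extension; only `"one_vs_one"` is provided.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(C = 1, tol = 1e-4, max_iter = 1000L,
                              multiclass = "one_vs_one") {
  structure(list(C = check_number(C, "C", min = 0, strict = TRUE),
                 tol = check_number(tol, "tol", min = 0, strict = TRUE),
                 max_iter = check_count(max_iter, "max_iter"),
                 multiclass = match.arg(multiclass, "one_vs_one")),
            class = "classifier_config")
}

#' Train a binary linear SVM
#'
#' Approximately minimizes the standard soft-margin objective
#' `0.5 * ||w||^2 + C * sum(max(0, 1 - y_i * (w . x_i + b)))` by dual
#' coordinate descent with deterministic cyclic sweeps. The bias is handled
#' by augmenting each sample with a constant feature, so it is weakly
#' regularized together with `w` (the convention used by fast linear-SVM
#' solvers). Non-convergence within `max_iter` sweeps is flagged in the
#' result, not silent.
#'
#' @param X Trials x features numeric matrix.
#' @param y Labels in `{-1, +1}` (or any two values; the larger maps to +1).
#' @param cfg A [classifier_config()].
#' @return A `binary_svm` list: `w`, `bias`, `converged`, `iterations`,
#'   `levels` (original labels mapped to -1/+1).
#' @export
train_binary_svm <- function(X, y, cfg = classifier_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) >= 1L)
  lev <- sort(unique(y))
  if (length(lev) != 2L) abort("binary SVM needs exactly two classes present")
  yy <- ifelse(y == lev[2], 1, -1)
  fit <- cpp_svm_train(X, as.numeric(yy), cfg$C, cfg$tol, cfg$max_iter)
  structure(list(w = as.numeric(fit$w), bias = fit$bias,
                 converged = fit$converged, iterations = fit$iterations,
                 levels = lev),
            class = "binary_svm")
}

#' @describeIn train_binary_svm Decision values `X %*% w + bias` (positive
#'   means the higher-sorted level).
#' @param object A `binary_svm`.
#' @param newdata Matrix of samples to score.
#' @param ... Unused.
#' @export
predict.binary_svm <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w + object$bias)
}

#' Train a one-vs-one multiclass linear SVM
#'
#' Fits one binary SVM per unordered class pair. Prediction is by majority
#' vote over the pairwise decisions; vote ties are broken by the largest
#' summed signed pairwise decision margin, then by the lowest class id, so
#' predictions are deterministic.
#'
#' @param X Trials x features matrix.
#' @param y Integer class labels; every class in `sort(unique(y))` must have
#'   at least one trial.
#' @param cfg A [classifier_config()].
#' @return A `linear_model` with one `binary_svm` per class pair.
#' @export
train_multiclass <- function(X, y, cfg = classifier_config()) {
  X <- as.matrix(X)
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2L) abort("need at least two classes")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  fits <- lapply(pairs, function(p) {
    idx <- y %in% p
    # orient the pair so +1 is the first (lower) class of the pair
    fit <- train_binary_svm(X[idx, , drop = FALSE],
                            ifelse(y[idx] == p[1], 1, -1), cfg)
    list(classes = p, fit = fit)
  })
  structure(list(pairs = fits, classes = classes, cfg = cfg),
            class = "linear_model")
}

#' @describeIn train_multiclass Predict class labels by pairwise voting.
#' @param object A `linear_model`.
#' @param newdata Matrix of samples to classify.
#' @param ... Unused.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  K <- length(object$classes)
  n <- nrow(newdata)
  votes <- matrix(0L, n, K)
  margin <- matrix(0, n, K)
  for (pf in object$pairs) {
    a <- match(pf$classes[1], object$classes)
    b <- match(pf$classes[2], object$classes)
    f <- predict(pf$fit, newdata)  # positive -> class a (oriented +1)
    votes[, a] <- votes[, a] + (f >= 0)
    votes[, b] <- votes[, b] + (f < 0)
    margin[, a] <- margin[, a] + f
    margin[, b] <- margin[, b] - f
  }
  vapply(seq_len(n), function(i) {
    best <- 1L
    for (k in seq_len(K)[-1]) {
      if (votes[i, k] > votes[i, best] ||
          (votes[i, k] == votes[i, best] && margin[i, k] > margin[i, best])) {
        best <- k
      }
    }
    object$classes[best]
  }, integer(1))
}

#' Leave-one-trial-out cross-validation scheme
#'
#' The outer testing regime: k-fold cross-validation with k equal to the
#' number of trials, so each fold holds out exactly one trial and trains on
#' all the others.
#'
#' @param patterns A [pattern_set()] (or anything with >= `n_classes + 1`
#'   trials; pass a pattern set for label-aware validation).
#' @return A `cv_scheme`: list of folds, each with `train` and `test`
#'   index vectors; attribute `k`.
#' @export
make_loto_scheme <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  n <- nrow(patterns$matrix)
  n_classes <- length(unique(patterns$labels))
  if (n < n_classes + 1L) abort("too few trials for leave-one-trial-out")
  folds <- lapply(seq_len(n), function(i) {
    list(train = setdiff(seq_len(n), i), test = i)
  })
  structure(folds, k = n, class = "cv_scheme")
}

# z-scoring statistics from training trials only (sd 0 guarded to 1)
train_zscore_stats <- function(X, train) {
  m <- colMeans(X[train, , drop = FALSE])
  s <- apply(X[train, , drop = FALSE], 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(center = m, scale = s)
}

#' Nested cross-validated decoding
#'
#' The full decoding analysis for one subject and ROI. For every outer
#' leave-one-trial-out fold: (1) searchlight feature selection — scoring and
#' the top-`n_select` cut — is computed on the training trials only, so no
#' information from the held-out trial can leak into the features
#' (`selection = "nested"`, the default); (2) voxels are z-scored with
#' training-fold statistics; (3) a one-vs-one linear SVM is trained on the
#' training trials restricted to the selected voxels and the held-out trial
#' is predicted. Accuracy is the proportion of correctly predicted held-out
#' trials. The reported information map is recomputed from all trials — it
#' is the subject's map for group analysis, never used for accuracy.
#'
#' `selection = "whole"` deliberately performs selection on all trials
#' including the test trial. It exists only to demonstrate the optimistic
#' bias of non-nested ("double-dipped") feature selection and must not be
#' used for inference.
#'
#' @param patterns A [pattern_set()].
#' @param mask The source [roi_mask()].
#' @param sl_spec A [searchlight_spec()].
#' @param n_select Voxels to select per fold (default 100).
#' @param cfg A [classifier_config()].
#' @param inner_folds Stratified folds for searchlight scoring (default 5).
#' @param selection `"nested"` (leakage-safe, default) or `"whole"`
#'   (diagnostic only).
#' @param condition Restrict the analysis to `"cued"` or `"free"` trials;
#'   default `"both"` collapses across conditions.
#' @return A `decoding_result`: `accuracy`, per-trial `trials` tibble,
#'   `confusion` matrix, per-fold selected voxel lists, and the whole-data
#'   `information_map`.
#' @export
cross_validate_decoding <- function(patterns, mask,
                                    sl_spec = searchlight_spec(),
                                    n_select = 100L,
                                    cfg = classifier_config(),
                                    inner_folds = 5L,
                                    selection = c("nested", "whole"),
                                    condition = c("both", "cued", "free")) {
  selection <- match.arg(selection)
  condition <- match.arg(condition)
  stopifnot(inherits(patterns, "pattern_set"))
  if (condition != "both") {
    keep <- which(patterns$condition == condition)
    patterns <- pattern_set(patterns$matrix[keep, , drop = FALSE],
                            patterns$labels[keep], patterns$condition[keep],
                            patterns$voxel_index, patterns$mask_name)
  }
  scheme <- make_loto_scheme(patterns)
  classes <- sort(unique(patterns$labels))
  X <- patterns$matrix
  n <- nrow(X)

  nbhd <- all_neighborhood_columns(mask, sl_spec)
  whole_scores <- NULL
  if (selection == "whole") {
    whole_scores <- score_searchlights(patterns, mask, sl_spec, inner_folds,
                                       cfg, .nbhd = nbhd)
    whole_cols <- info_map_columns(whole_scores, n_select, mask)
  }

  predicted <- integer(n)
  fold_selections <- vector("list", length(scheme))
  for (f in seq_along(scheme)) {
    train <- scheme[[f]]$train
    test <- scheme[[f]]$test
    if (selection == "nested") {
      sc <- score_searchlights(patterns, mask, sl_spec, inner_folds, cfg,
                               trials = train, .nbhd = nbhd)
      cols <- info_map_columns(sc, n_select, mask)
    } else {
      cols <- whole_cols
    }
    fold_selections[[f]] <- cols
    zs <- train_zscore_stats(X, train)
    Xz <- sweep(sweep(X[, cols, drop = FALSE], 2, zs$center[cols]), 2,
                zs$scale[cols], `/`)
    model <- train_multiclass(Xz[train, , drop = FALSE],
                              patterns$labels[train], cfg)
    predicted[test] <- predict(model, Xz[test, , drop = FALSE])
  }

  confusion <- table(factor(patterns$labels, levels = classes),
                     factor(predicted, levels = classes))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  accuracy <- mean(predicted == patterns$labels)

  final_scores <- whole_scores %||%
    score_searchlights(patterns, mask, sl_spec, inner_folds, cfg,
                       .nbhd = nbhd)
  info_map <- build_information_map(final_scores, n_select)

  structure(list(
    accuracy = accuracy,
    trials = tibble(trial = seq_len(n), fold = seq_len(n),
                    condition = patterns$condition,
                    true = patterns$labels, predicted = predicted,
                    correct = predicted == patterns$labels),
    confusion = confusion,
    classes = classes,
    fold_selections = fold_selections,
    information_map = info_map,
    score_map = final_scores,
    selection = selection,
    condition = condition,
    n_select = as.integer(n_select),
    roi_name = patterns$mask_name,
    cfg = cfg, sl_spec = sl_spec, inner_folds = as.integer(inner_folds)
  ), class = "decoding_result")
}

# columns (mask voxel order) of the information map built from a score map
info_map_columns <- function(scores, n_select, mask) {
  im <- build_information_map(scores, n_select)
  match(voxel_key(im$selected), voxel_key(mask$voxels))
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result '%s' (%s trials, %s selection): accuracy %.3f on %d trials>\n",
              x$roi_name, x$condition, x$selection, x$accuracy,
              nrow(x$trials)))
  invisible(x)
}

#' Permutation estimate of chance decoding
#'
#' Re-runs the full nested pipeline with class labels permuted within
#' condition (cued labels shuffled among cued trials, free among free), so
#' the null preserves the design's block structure. Returns the null
#' accuracy distribution and the empirical p-value
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param patterns A [pattern_set()].
#' @param mask The source [roi_mask()].
#' @param observed Observed accuracy to test; if `NULL`, the nested pipeline
#'   is first run on the unpermuted labels.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @inheritParams cross_validate_decoding
#' @return A `permutation_test` list: `observed`, `null` (length `n_perm`),
#'   `p_value`, `n_perm`.
#' @export
permutation_chance <- function(patterns, mask, sl_spec = searchlight_spec(),
                               n_select = 100L, cfg = classifier_config(),
                               inner_folds = 5L, n_perm = 20L, seed = 1L,
                               observed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  if (is.null(observed)) {
    observed <- cross_validate_decoding(patterns, mask, sl_spec, n_select,
                                        cfg, inner_folds)$accuracy
  }
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- permute_labels_within_condition(patterns)
      cross_validate_decoding(perm, mask, sl_spec, n_select, cfg,
                              inner_folds)$accuracy
    }, numeric(1))
  })
  structure(list(observed = observed, null = null_acc,
                 p_value = (1 + sum(null_acc >= observed)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "permutation_test")
}

# shuffle labels within each condition, preserving everything else
permute_labels_within_condition <- function(patterns) {
  labels <- patterns$labels
  for (cond in unique(patterns$condition)) {
    idx <- which(patterns$condition == cond)
    labels[idx] <- labels[idx][sample.int(length(idx))]
  }
  pattern_set(patterns$matrix, labels, patterns$condition,
              patterns$voxel_index, patterns$mask_name)
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test: observed %.3f, null mean %.3f (%d perms), p = %.4f>\n",
              x$observed, mean(x$null), x$n_perm, x$p_value))
  invisible(x)
}
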