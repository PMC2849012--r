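separable_clouds <- function(n_per = 10, gap = 10, seed = 51) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2) + gap, n_per, 2))
  list(X = X, y = rep(c(-1, 1), each = n_per))
}

test_that("binary SVM separates well-separated clouds with zero errors", {
  d <- separable_clouds()
  fit <- train_binary_svm(d$X, d$y)
  expect_true(fit$converged)
  expect_true(all(sign(predict(fit, d$X)) == d$y))
  expect_error(train_binary_svm(d$X, rep(1, 20)), "two classes")
})

test_that("one-feature boundary falls inside the class gap", {
  X <- matrix(c(-3, -2, -1.5, 1.5, 2, 3), ncol = 1)
  y <- sign(X[, 1])
  fit <- train_binary_svm(X, y)
  boundary <- -fit$bias / fit$w[1]
  expect_gt(boundary, -1.5)
  expect_lt(boundary, 1.5)
})

test_that("duplicated feature columns leave decision values unchanged", {
  d <- separable_clouds(gap = 4, seed = 52)
  fit1 <- train_binary_svm(d$X, d$y)
  # oracle: same data with each column duplicated; w splits across copies
  fit2 <- train_binary_svm(cbind(d$X, d$X), d$y)
  dec1 <- predict(fit1, d$X)
  dec2 <- predict(fit2, cbind(d$X, d$X))
  expect_equal(dec2, dec1, tolerance = 1e-2)
  expect_true(all(sign(dec1) == sign(dec2)))
})

test_that("solver agrees with the libsvm implementation on toy data", {
  skip_if_not_installed("e1071")
  d <- separable_clouds(gap = 3, seed = 53)
  ours <- train_binary_svm(d$X, d$y)
  ref <- e1071::svm(d$X, factor(d$y), kernel = "linear", cost = 1,
                    scale = FALSE)
  ref_pred <- as.numeric(as.character(predict(ref, d$X)))
  expect_equal(sign(predict(ours, d$X)), ref_pred)
  # weight vectors proportional (bias conventions differ slightly)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  cosine <- sum(ours$w * w_ref) /
    sqrt(sum(ours$w^2) * sum(w_ref^2))
  expect_gt(abs(cosine), 0.9)  # libsvm may orient the pair the other way
})

test_that("one-vs-one reduces to the binary SVM for two classes", {
  d <- separable_clouds(gap = 6, seed = 54)
  y12 <- ifelse(d$y > 0, 2L, 1L)
  multi <- train_multiclass(d$X, y12)
  bin <- train_binary_svm(d$X, ifelse(y12 == 1, 1, -1))
  pred_multi <- predict(multi, d$X)
  pred_bin <- ifelse(predict(bin, d$X) >= 0, 1L, 2L)
  expect_equal(pred_multi, pred_bin)
})

test_that("three separable clouds decode perfectly; votes match enumeration", {
  set.seed(55)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(16), 8, 2) + rep(centers[k, ], each = 8)
  }))
  y <- rep(1:3, each = 8)
  model <- train_multiclass(X, y)
  expect_equal(predict(model, X), y)
  # hand oracle: enumerate pairwise winners and majority votes per sample
  for (i in c(1, 9, 20)) {
    votes <- integer(3)
    for (pf in model$pairs) {
      f <- predict(pf$fit, X[i, , drop = FALSE])
      winner <- if (f >= 0) pf$classes[1] else pf$classes[2]
      votes[winner] <- votes[winner] + 1L
    }
    expect_equal(predict(model, X[i, , drop = FALSE]), which.max(votes))
  }
})

test_that("three-way vote ties break by margin sum then lowest class", {
  # hand-built cyclic model: 1 beats 2, 2 beats 3, 3 beats 1 -> one vote each
  mk_fit <- function(w, b) {
    structure(list(w = w, bias = b, converged = TRUE, iterations = 1L,
                   levels = c(-1, 1)), class = "binary_svm")
  }
  model <- structure(list(
    pairs = list(
      list(classes = c(1L, 2L), fit = mk_fit(c(0, 0), 1)),    # f = +1 -> 1
      list(classes = c(1L, 3L), fit = mk_fit(c(0, 0), -2)),   # f = -2 -> 3
      list(classes = c(2L, 3L), fit = mk_fit(c(0, 0), 1))),   # f = +1 -> 2
    classes = 1:3, cfg = classifier_config()), class = "linear_model")
  x <- matrix(0, 1, 2)
  # margins: class1 = +1 - (-2) = 3 wait: class1 gets +1 (vs 2) + (-2) (vs 3) = -1
  # class2 = -1 + 1 = 0 ; class3 = +2 - 1 = 1 -> margin tie-break picks 3
  expect_equal(predict(model, x), 3L)
  # exact symmetric margins: all zero -> lowest class id wins
  model0 <- model
  for (i in 1:3) model0$pairs[[i]]$fit$bias <- c(1, -1, 1)[i] * 0
  # all decisions 0 -> f >= 0 votes for first class of each pair:
  # votes: 1 gets 2, 2 gets 1, 3 gets 0 -> class 1 outright
  expect_equal(predict(model0, x), 1L)
})

test_that("missing classes are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_multiclass(X, rep(1L, 10)), "two classes")
})

test_that("leave-one-trial-out scheme has k = n folds partitioning trials", {
  d <- generate_trial_design(design_config(seed = 61))
  mask <- solid_mask(4)
  sim <- synthesize_run(d, mask, signal_config(seed = 61))
  pats <- extract_trial_patterns(linear_detrend(sim$run),
                                 shift_onsets(d, 2, 2), mask, 2)
  sch <- make_loto_scheme(pats)
  expect_equal(attr(sch, "k"), 51L)  # 21 cued + 30 free
  tested <- sort(unlist(lapply(sch, `[[`, "test")))
  expect_equal(tested, 1:51)
  for (f in sch[c(1, 25, 51)]) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(sort(c(f$train, f$test)), 1:51)
  }
  small <- pattern_set(pats$matrix[1:3, ], c(1L, 2L, 3L),
                       pats$condition[1:3], pats$voxel_index)
  expect_error(make_loto_scheme(small), "too few")
})

test_that("predictions are invariant to common positive feature rescaling", {
  d <- separable_clouds(gap = 8, seed = 62)
  fit1 <- train_binary_svm(d$X, d$y, classifier_config(C = 1))
  # rescale features by s; with C scaled by 1/s^2 the separable solution
  # predicts identically on rescaled inputs
  s <- 5
  fit2 <- train_binary_svm(d$X * s, d$y, classifier_config(C = 1 / s^2))
  expect_equal(sign(predict(fit2, d$X * s)), sign(predict(fit1, d$X)))
})

test_that("nested decoding result satisfies its accounting contracts", {
  subj <- small_subject(seed = 70, effect_size = 1.5)
  res <- cross_validate_decoding(subj$patterns, subj$mask, n_select = 20)
  cm <- res$confusion
  expect_equal(res$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(unname(rowSums(cm)),
               unname(as.vector(table(subj$patterns$labels))))
  expect_equal(nrow(res$trials), nrow(subj$patterns$matrix))
  expect_equal(length(res$fold_selections), nrow(res$trials))
  expect_true(all(vapply(res$fold_selections, length, integer(1)) == 20))
  # glance/tidy accessors
  g <- glance(res)
  expect_equal(g$accuracy, res$accuracy)
  expect_equal(nrow(tidy(res)), nrow(res$trials))
})

test_that("decoding is reproducible bit-for-bit", {
  subj <- small_subject(seed = 71)
  r1 <- cross_validate_decoding(subj$patterns, subj$mask, n_select = 15)
  r2 <- cross_validate_decoding(subj$patterns, subj$mask, n_select = 15)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$trials$predicted, r2$trials$predicted)
  expect_identical(r1$information_map$selected, r2$information_map$selected)
})

test_that("per-condition filtering restricts the analysis", {
  subj <- small_subject(seed = 72, effect_size = 2)
  res_cued <- cross_validate_decoding(subj$patterns, subj$mask,
                                      n_select = 15, condition = "cued")
  expect_equal(nrow(res_cued$trials),
               sum(subj$patterns$condition == "cued"))
})

test_that("permutation p-value follows its formula bounds", {
  subj <- small_subject(seed = 73, effect_size = 0)
  # observed below every null value -> p = 1 (use observed = 0 shortcut)
  pt <- permutation_chance(subj$patterns, subj$mask, n_select = 15,
                           n_perm = 3, seed = 2, observed = 0)
  expect_equal(pt$p_value, 1)
  expect_length(pt$null, 3)
  # observed above every null -> p = 1/(n_perm + 1)
  pt2 <- permutation_chance(subj$patterns, subj$mask, n_select = 15,
                            n_perm = 3, seed = 2, observed = 1.01)
  expect_equal(pt2$p_value, 1 / 4)
})
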