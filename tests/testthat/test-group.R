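mk_map <- function(vox, grid = c(6L, 6L, 6L), subject = NA) {
  structure(list(selected = episearch:::lex_sort_voxels(vox),
                 n_select = nrow(vox), roi_name = "HC", grid_shape = grid,
                 subject = subject), class = "information_map")
}

test_that("heat map counts subjects per voxel with ceiling n_subjects", {
  v <- matrix(c(2L, 3L, 1L), 1, 3)
  maps10 <- lapply(1:10, function(s) mk_map(v, subject = s))
  heat <- aggregate_heat_map(maps10)
  expect_equal(max(heat$counts), 10L)         # the ceiling is exactly n
  expect_equal(heat$counts[3, 4, 2], 10L)
  expect_equal(sum(heat$counts), 10L)

  disjoint <- lapply(0:4, function(k) mk_map(matrix(c(k, 0L, 0L), 1, 3)))
  h2 <- aggregate_heat_map(disjoint)
  expect_equal(max(h2$counts), 1L)

  expect_error(aggregate_heat_map(list()), "at least one")
})

test_that("heat totals conserve the summed map sizes", {
  set.seed(81)
  maps <- lapply(1:7, function(s) {
    vox <- unique(matrix(sample(0:5, 30, replace = TRUE), ncol = 3))
    mk_map(vox, subject = s)
  })
  heat <- aggregate_heat_map(maps)
  expect_equal(sum(heat$counts),
               sum(vapply(maps, function(m) nrow(m$selected), integer(1))))
})

test_that("grid mismatch without resampling is an error", {
  a <- mk_map(matrix(c(1L, 1L, 1L), 1, 3), grid = c(6L, 6L, 6L))
  b <- mk_map(matrix(c(1L, 1L, 1L), 1, 3), grid = c(8L, 8L, 8L))
  expect_error(aggregate_heat_map(list(a, b)), "different grids")
})

test_that("binomial tail p-values match closed forms and enumeration", {
  maps <- lapply(1:10, function(s) mk_map(matrix(c(2L, 3L, 1L), 1, 3),
                                          subject = s))
  heat <- aggregate_heat_map(maps)
  pmap <- binomial_voxel_pvalues(heat, 0.5)
  expect_equal(pmap$p[3, 4, 2], 0.5^10)           # k = 10: single tail term
  expect_equal(pmap$p[1, 1, 1], 1.0)              # k = 0
  # k = 3, n = 10, p0 = 0.1 against term-by-term choose() enumeration
  pmap2 <- binomial_voxel_pvalues(heat, 0.1)
  oracle <- sum(vapply(3:10, function(j) {
    choose(10, j) * 0.1^j * 0.9^(10 - j)
  }, numeric(1)))
  k3 <- episearch:::binom_upper_tail(3, 10, 0.1)
  expect_equal(k3, oracle, tolerance = 1e-14)
  expect_error(binomial_voxel_pvalues(heat, 0), "p0")
  expect_error(binomial_voxel_pvalues(heat, 1), "p0")
})

test_that("binomial tails agree with brute-force enumeration for n <= 20", {
  for (n in c(1, 5, 10, 20)) {
    for (p0 in c(0.05, 0.3, 0.5, 0.9)) {
      ours <- episearch:::binom_upper_tail(0:n, n, p0)
      oracle <- vapply(0:n, function(k) {
        if (k == 0) return(1)
        sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
      }, numeric(1))
      expect_equal(ours, oracle, tolerance = 1e-12)
      # and with the distribution function as a second, independent route
      expect_equal(ours, pbinom((0:n) - 1, n, p0, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("p-values decrease monotonically in frequency", {
  tails <- episearch:::binom_upper_tail(0:10, 10, 0.25)
  expect_true(all(diff(tails) < 0))
  expect_true(all(tails > 0 & tails <= 1))
})

test_that("thresholding keeps strictly sub-alpha voxels", {
  maps <- lapply(1:10, function(s) {
    mk_map(rbind(c(2L, 3L, 1L), if (s <= 3) c(0L, 0L, 0L)), subject = s)
  })
  heat <- aggregate_heat_map(maps)
  pmap <- binomial_voxel_pvalues(heat, 0.2)
  sig <- threshold_map(pmap, 0.001)
  # k = 10 at p0 = 0.2: p = 0.2^10 ~ 1e-7 < 0.001; k = 3: p ~ 0.32
  expect_equal(nrow(sig), 1L)
  expect_equal(unname(sig[1, ]), c(2L, 3L, 1L))
  # alpha below the k = n tail -> empty
  expect_equal(nrow(threshold_map(pmap, 1e-9)), 0L)
  # alpha = 0.999 keeps everything with p < 0.999 (all voxels with k >= 1)
  wide <- threshold_map(pmap, 0.999)
  expect_equal(nrow(wide), 2L)
  # bonferroni divides alpha by the tested voxel count
  sig_b <- threshold_map(pmap, 0.001, bonferroni = TRUE, n_tests = 2)
  expect_equal(attr(sig_b, "alpha_effective"), 0.0005)
})

test_that("null cohorts produce conservative voxelwise false positives", {
  # independent random maps of fixed size: the fraction of voxels called at
  # alpha must stay near or below alpha under the matching binomial null
  set.seed(83)
  grid <- c(12L, 12L, 12L)
  n_vox <- prod(grid)
  n_sel <- 100L
  frac <- replicate(20, {
    maps <- lapply(1:10, function(s) {
      idx <- sample.int(n_vox, n_sel) - 1L
      vox <- cbind(idx %% 12L, (idx %/% 12L) %% 12L, idx %/% 144L)
      mk_map(vox, grid = grid, subject = s)
    })
    pmap <- binomial_voxel_pvalues(aggregate_heat_map(maps), n_sel / n_vox)
    nrow(threshold_map(pmap, 0.01)) / n_vox
  })
  expect_lt(mean(frac), 0.011)
})

test_that("heat maps expose a frequency table and a slice plot", {
  maps <- lapply(1:4, function(s) mk_map(matrix(c(2L, 3L, 1L, s, 0L, 0L),
                                                2, 3, byrow = TRUE),
                                         subject = s))
  heat <- aggregate_heat_map(maps)
  tab <- tidy(heat)
  expect_named(tab, c("x", "y", "z", "frequency"))
  expect_equal(tab$frequency[1], 4L)  # the shared voxel leads
  expect_equal(sum(tab$frequency), 8L)
  expect_s3_class(autoplot(heat), "ggplot")
})

test_that("identity-affine resampling is a no-op and mismatches error", {
  m <- mk_map(matrix(c(1L, 2L, 3L, 4L, 5L, 0L), 2, 3, byrow = TRUE))
  eye <- diag(4)
  out <- resample_information_map(m, eye, eye, c(6L, 6L, 6L))
  expect_equal(out$selected, m$selected)
  # half-resolution target: voxels land on doubled indices
  shrink <- diag(c(2, 2, 2, 1))
  out2 <- resample_information_map(m, shrink, eye, c(12L, 12L, 12L))
  expect_equal(out2$selected, episearch:::lex_sort_voxels(m$selected * 2L))
  expect_error(resample_information_map(m, shrink, eye, c(6L, 6L, 6L)),
               "outside the target grid")
})
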