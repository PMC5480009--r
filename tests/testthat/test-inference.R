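test_that("kernel estimation normalizes confusion columns", {
  expect_equal(unname(estimate_kernel(diag(3) * 7)), diag(3),
               tolerance = 1e-12)
  cm <- matrix(0, 3, 3)
  cm[, 1] <- c(8, 0, 2)  # classified-positive column
  cm[, 2] <- c(1, 1, 1)
  cm[, 3] <- c(2, 2, 6)
  k <- estimate_kernel(cm)
  expect_equal(unname(k[, 1]), c(0.8, 0, 0.2), tolerance = 1e-12)
  expect_equal(unname(k[, 2]), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(colSums(k)), rep(1, 3), tolerance = 1e-9)
  # uniform table -> every column uniform
  expect_equal(unname(estimate_kernel(matrix(4, 3, 3))),
               matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # zero column falls back to the identity distribution
  cm0 <- cm
  cm0[, 2] <- 0
  expect_equal(unname(estimate_kernel(cm0)[, 2]), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("replicate correction preserves the total count", {
  k <- estimate_kernel(matrix(c(40, 2, 8, 0, 30, 10, 5, 6, 99), 3, 3))
  set.seed(2)
  for (i in 1:20) {
    counts <- c(positive = rpois(1, 50), negative = rpois(1, 50),
                neutral = rpois(1, 100))
    corrected <- draw_true_counts(counts, k)
    expect_identical(sum(corrected), as.integer(sum(counts)))
    expect_true(all(corrected >= 0L))
  }
  # identity kernel correction is the identity map
  expect_identical(draw_true_counts(c(3, 1, 1), identity_kernel()),
                   c(positive = 3L, negative = 1L, neutral = 1L))
})

test_that("identity-kernel bootstrap centers on observed proportions", {
  est <- bootstrap_proportions(c(positive = 200, negative = 200,
                                 neutral = 600),
                               identity_kernel(), n_boot = 4000, seed = 3L)
  expect_equal(unname(est$proportions), c(0.2, 0.2, 0.6), tolerance = 0.01)
  expect_lte(est$ci_low, 1)
  expect_gte(est$ci_high, 1)
  expect_equal(est$ratio_point, 1, tolerance = 0.05)
  # percentile construction brackets the replicate median
  expect_lte(est$ci_low, median(est$replicates))
  expect_gte(est$ci_high, median(est$replicates))
  # corrected proportions sum to 1
  expect_equal(sum(est$proportions), 1, tolerance = 1e-9)
})

test_that("bootstrap is deterministic under a fixed seed", {
  k <- estimate_kernel(matrix(c(40, 2, 8, 0, 30, 10, 5, 6, 99), 3, 3))
  counts <- c(positive = 150, negative = 250, neutral = 600)
  e1 <- bootstrap_proportions(counts, k, n_boot = 500, seed = 7L)
  e2 <- bootstrap_proportions(counts, k, n_boot = 500, seed = 7L)
  expect_identical(e1$replicates, e2$replicates)
  expect_identical(e1$ratio_point, e2$ratio_point)
})

test_that("degenerate regimes are rejected with diagnostics", {
  all_neg_kernel <- matrix(c(0, 1, 0, 0, 1, 0, 0, 1, 0), 3, 3)
  expect_error(
    bootstrap_proportions(c(50, 50, 100), all_neg_kernel, n_boot = 200,
                          seed = 1L),
    "zero corrected positive")
  expect_error(bootstrap_proportions(c(0, 0, 100), identity_kernel(),
                                     n_boot = 100, seed = 1L),
               "no positively or negatively")
})

test_that("null test is centered, powered, and symmetric", {
  counts <- c(positive = 500, negative = 500, neutral = 1000)
  # an observed ratio at the null center is not rejected
  center <- null_ratio_test(counts, 1.0, n_boot = 3000, seed = 5L)
  expect_gt(center$p_two_sided, 0.5)
  # a 2:1 imbalance at this size is decisively rejected
  extreme <- null_ratio_test(counts, 2.0, n_boot = 10000, seed = 5L)
  expect_lt(extreme$p_two_sided, 0.001)
  # symmetry: swapping counts and inverting the ratio gives a similar p
  asym <- c(positive = 300, negative = 700, neutral = 1000)
  swapped <- c(positive = 700, negative = 300, neutral = 1000)
  p1 <- null_ratio_test(asym, 1.3, n_boot = 8000, seed = 9L)$p_two_sided
  p2 <- null_ratio_test(swapped, 1 / 1.3, n_boot = 8000, seed = 10L)$p_two_sided
  expect_lt(abs(p1 - p2), 0.02)
  expect_error(null_ratio_test(c(0, 0, 10), 1, n_boot = 10, seed = 1L),
               "no positively or negatively")
  expect_error(null_ratio_test(counts, Inf, n_boot = 10, seed = 1L),
               "observed_ratio")
})

test_that("odd positive+negative totals preserve the exact dataset size", {
  # 7 polar messages: the null allocates 3/4 or 4/3 per replicate
  counts <- c(positive = 3, negative = 4, neutral = 10)
  res <- null_ratio_test(counts, 1.0, n_boot = 500, seed = 2L)
  expect_true(res$p_two_sided > 0 && res$p_two_sided <= 1)
})
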