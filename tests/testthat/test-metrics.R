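test_that("histogram binning is left-closed with a right-inclusive last bin", {
  h <- disparity_histogram(c(0, 0.5, 1), n_bins = 2)
  expect_equal(h$counts, c(1, 2))
  expect_equal(h$n_total, 2L)
  # conservation on random samples
  set.seed(2)
  x <- runif(1234)
  h2 <- disparity_histogram(x, 100)
  expect_equal(sum(h2$counts), 1234)
  expect_equal(h2$n_samples, 1234L)
  expect_error(disparity_histogram(numeric(0)), "empty")
  expect_error(disparity_histogram(c(0.2, 1.2)), "0, 1")
})

test_that("uniform samples fill bins within binomial fluctuation", {
  set.seed(4)
  x <- runif(10000)
  h <- disparity_histogram(x, 100)
  # each count ~ Binomial(10000, 0.01): sd = sqrt(99) ~ 9.9
  expect_true(all(abs(h$counts - 100) < 5 * sqrt(10000 * 0.01 * 0.99)))
  expect_equal(distribution_width_index(h), 1)  # all bins occupied
  expect_lt(peak_ratio(h), 2)                   # flat distribution
})

test_that("peak ratio follows the definition with the alpha-position bin", {
  # 4 bins, alpha = 25%: alpha bin index floor(0.25*4)+1 = 2 -> count 4
  samples <- c(rep(0.1, 8), rep(0.3, 4), rep(0.6, 2), rep(0.9, 1))
  h <- disparity_histogram(samples, n_bins = 4, alpha_percent = 25)
  expect_equal(h$counts, c(8, 4, 2, 1))
  expect_equal(h$h_alpha, 4)
  expect_equal(peak_ratio(h), 2)
  # flat counts give PR = 1
  hflat <- disparity_histogram(rep(c(0.1, 0.3, 0.6, 0.9), 5), 4)
  expect_equal(peak_ratio(hflat), 1)
  # empty alpha bin engages the zero-count guard: PR = Hmax / 1
  hg <- disparity_histogram(rep(0.005, 37), 100)
  expect_equal(hg$h_alpha, 0)
  expect_equal(peak_ratio(hg), 37)
})

test_that("DWI counts occupied bins", {
  h <- disparity_histogram(c(0.05, 0.05, 0.05, 0.6), n_bins = 4)
  expect_equal(h$counts, c(3, 0, 1, 0))
  expect_equal(distribution_width_index(h), 0.5)
  h1 <- disparity_histogram(rep(0.42, 100), 100)
  expect_equal(distribution_width_index(h1), 0.01)
})

test_that("PR is invariant under uniform count rescaling; DWI under any positive scaling", {
  set.seed(6)
  x <- rexp(800, 15)
  x <- x[x <= 1]
  h <- disparity_histogram(x, 50)
  h3 <- disparity_histogram(rep(x, 3), 50)  # triples every count
  expect_equal(peak_ratio(h3), peak_ratio(h))
  expect_equal(distribution_width_index(h3), distribution_width_index(h))
})

test_that("DWI does not increase as distributions concentrate", {
  # nested family: progressively tighter exponential decay
  set.seed(8)
  u <- runif(4000)
  dwis <- vapply(c(5, 10, 20, 40, 80), function(rate) {
    x <- pmin(-log(u) / rate, 1)   # same uniforms -> nested concentration
    distribution_width_index(disparity_histogram(x, 100))
  }, numeric(1))
  expect_true(all(diff(dwis) <= 0))
})

test_that("KS matrix is symmetric, zero-diagonal and matches the brute-force sup", {
  set.seed(10)
  samples <- lapply(1:9, function(k) runif(30 + 5 * k, 0, 0.2 + 0.08 * k))
  km <- ks_matrix(samples)
  expect_equal(km$d, t(km$d))
  expect_true(all(diag(km$d) == 0))
  expect_true(all(km$d >= 0 & km$d <= 1))
  for (i in c(1, 4)) for (j in c(6, 9))
    expect_equal(km$d[i, j], oracle_ks(samples[[i]], samples[[j]]))
  # worked cases
  expect_equal(oracle_ks(c(0.1, 0.2), c(0.8, 0.9)), 1)
  same <- lapply(1:9, function(k) c(0.1, 0.4, 0.7))
  expect_true(all(ks_matrix(same)$d == 0))
  two <- samples; two[[1]] <- c(0.1, 0.5); two[[2]] <- c(0.3, 0.7)
  expect_equal(ks_matrix(two)$d[1, 2], 0.5)
  bad <- samples; bad[[3]] <- numeric(0)
  expect_error(ks_matrix(bad), "insufficient")
})

test_that("classification thresholds partition the PR/DWI plane", {
  cfg <- adhesion_config()
  expect_identical(classify_adhesion(120, 0.25, cfg), "adhesion")
  expect_identical(classify_adhesion(30, 0.5, cfg), "non-adhesion")
  expect_identical(classify_adhesion(70, 0.35, cfg), "indeterminate")
  expect_identical(classify_adhesion(120, 0.5, cfg), "indeterminate")
  expect_identical(classify_adhesion(30, 0.25, cfg), "indeterminate")
})

test_that("group test: exact p-value for complete separation of 7 vs 13", {
  a <- 101:107
  b <- 1:13
  gt <- adhesion_group_test(a, b)
  # all group-a values above all group-b values: two-sided exact p = 2/C(20,7)
  expect_equal(gt$p_value, 2 / choose(20, 7), tolerance = 1e-12)
  expect_lt(gt$p_value, 0.01)
})

test_that("group test handles ties via enumeration consistently with the exact case", {
  set.seed(12)
  a <- rnorm(6)
  b <- rnorm(7, 1)
  no_ties <- adhesion_group_test(a, b)
  with_ties <- adhesion_group_test(round(a, 1), round(b, 1))
  expect_identical(with_ties$method, "exact (enumeration)")
  # enumeration on tie-free data reproduces the distribution-based p-value
  enum <- adhesion_group_test(c(a, max(a)), b)   # duplicate forces enumeration
  ref <- suppressWarnings(wilcox.test(c(a, max(a)), b)$p.value)
  expect_equal(enum$p_value, ref, tolerance = 0.05)
  expect_lte(abs(no_ties$p_value - with_ties$p_value), 0.05)
})

test_that("degenerate all-tied groups return p = 1 with a warning", {
  expect_warning(gt <- adhesion_group_test(rep(1, 5), rep(1, 8)), "tied")
  expect_equal(gt$p_value, 1)
  # identical (but non-constant) groups are far from significant
  x <- c(1, 2, 3, 4)
  gt2 <- adhesion_group_test(x, x)
  expect_gt(gt2$p_value, 0.9)
})
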