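# Bayesian bin-number selection and histogram construction.

test_that("log posterior matches high-precision term-by-term values", {
  # Expected values computed once with 40-digit log-gamma arithmetic.
  d <- cbind(c(0, 0.3, 0.7, 1))                 # counts (2, 2) at N = 2
  expect_equal(log_binning_posterior(d, 2), -0.980829253011726, tolerance = 1e-12)
  lp <- contourgate:::.log_posterior_from_counts
  expect_equal(lp(4, 1, 2, c(2, 2)), -0.980829253011726, tolerance = 1e-12)
  # fully clumped counts (4, 0) support finer structure than spread (2, 2)
  expect_equal(lp(4, 1, 2, c(4, 0)), 1.475906519809578, tolerance = 1e-12)
  expect_gt(lp(4, 1, 2, c(4, 0)), lp(4, 1, 2, c(2, 2)))
  # empty bins are handled analytically: explicit zeros change nothing
  expect_equal(lp(12, 2, 2, c(5, 3, 0, 4)), lp(12, 2, 2, c(5, 3, 4)),
               tolerance = 1e-12)
  expect_equal(lp(12, 2, 2, c(5, 3, 0, 4)), -0.0212022076506029, tolerance = 1e-12)
  expect_equal(lp(30, 3, 2, c(4, 2, 7, 1, 0, 9, 3, 4)), 0.610029135994349,
               tolerance = 1e-12)

  set.seed(41)
  x1 <- cbind(c(0.05, 0.5, 0.51, 0.52, 0.53, 0.6, 0.61, 0.95, 0.96, 0.99))
  h1 <- build_histogram(x1, 3)
  expect_equal(sort(h1$counts[h1$counts > 0]), sort(c(1, 6, 3)))
  expect_equal(log_binning_posterior(x1, 3), -0.401001231726519, tolerance = 1e-10)
})

test_that("any data has posterior exactly zero at N = 1", {
  set.seed(1)
  for (D in 1:3) {
    x <- matrix(rnorm(60 * D), ncol = D)
    expect_identical(log_binning_posterior(x, 1), 0)
  }
})

test_that("posterior agrees with an independent dense-count oracle", {
  set.seed(7)
  cases <- list(matrix(runif(100), ncol = 1),
                matrix(rnorm(200), ncol = 2),
                matrix(c(rnorm(90), rnorm(90, 4)), ncol = 3))
  for (x in cases) {
    for (N in c(2, 3, 5, 8)) {
      expect_equal(log_binning_posterior(x, N), oracle_log_posterior(x, N),
                   tolerance = 1e-9)
    }
  }
})

test_that("optimal bin number equals an exhaustive independent scan", {
  set.seed(11)
  x <- matrix(runif(100), ncol = 1)
  scan <- vapply(1:40, function(N) oracle_log_posterior(x, N), 0)
  expect_identical(optimal_bin_number(x, N_max = 40), which.max(scan))

  y <- matrix(c(rnorm(300, 0, 0.5), rnorm(300, 5, 0.5)), ncol = 1)
  scan2 <- vapply(1:60, function(N) oracle_log_posterior(y, N), 0)
  expect_identical(optimal_bin_number(y, N_max = 60), which.max(scan2))
})

test_that("histogram counts are conserved and edges handled inclusively", {
  h <- build_histogram(cbind(c(0, 0.5, 1.0)), 2)
  expect_identical(h$counts, c(2L, 1L))  # 0.5 closes the first bin
  set.seed(5)
  for (D in 1:3) {
    x <- matrix(runif(400 * D), ncol = D)
    for (N in c(1, 3, 7)) {
      h <- build_histogram(x, N)
      expect_identical(sum(h$counts), nrow(x))
      expect_identical(h$level_max, max(h$counts))
    }
  }
})

test_that("binning is invariant under increasing affine channel transforms", {
  set.seed(9)
  x <- matrix(rnorm(500), ncol = 2)
  y <- x
  y[, 1] <- 3.7 * y[, 1] + 120
  y[, 2] <- 0.01 * y[, 2] - 5
  for (N in c(2, 6, 13)) {
    hx <- build_histogram(x, N); hy <- build_histogram(y, N)
    expect_identical(hx$counts, hy$counts)
    expect_identical(hx$keys, hy$keys)
    expect_equal(log_binning_posterior(x, N), log_binning_posterior(y, N),
                 tolerance = 1e-9)
  }
  expect_identical(optimal_bin_number(x, 30), optimal_bin_number(y, 30))
})

test_that("degenerate inputs are caught", {
  expect_warning(n1 <- optimal_bin_number(matrix(1, 50, 2)), "identical")
  expect_identical(n1, 1L)
  expect_warning(build_histogram(cbind(rnorm(20), rep(3, 20)), 4), "constant")
  expect_error(build_histogram(cbind(c(1, NA, 3)), 2), "non-finite")
  expect_error(build_histogram(cbind(rnorm(10)), 0), "positive")
  expect_error(build_histogram(matrix(rnorm(40), ncol = 2), 1e9), "capacity")
})
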