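# The distorted-Gaussian event simulator.

test_that("Box-Muller reproduces the closed form and standard moments", {
  expect_equal(box_muller(1, u1 = exp(-2), u2 = 0), 2)
  expect_equal(box_muller(1, u1 = exp(-0.5), u2 = 0.5), -1)
  set.seed(10)
  a <- box_muller(1000)
  set.seed(10)
  expect_identical(box_muller(1000), a)       # deterministic under a seed
  set.seed(11)
  z <- box_muller(1e5)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(var(z) - 1), 0.02)
})

test_that("the displacement rule applies the quadratic coupling to axis k2", {
  spec <- gaussian_component(c(100, 0, 7), c(10, 5, 2), 10, k1 = 1, k2 = 2,
                             s = 0.002)
  d1 <- c(2, 0)                                # deviates for axis k1
  dmat <- rbind(c(99, 1, 0.5), c(99, -1, 2))   # k1 column is ignored
  X <- contourgate:::.distort_axes(spec, d1, dmat)
  expect_equal(X[1, 1], 120)                   # 100 + 2 * 10
  expect_equal(X[1, 2], 5 + 0.002 * (2 * 10)^2)  # 0 + 1*5 + s*(d1*sd_k1)^2
  expect_equal(X[1, 3], 7 + 0.5 * 2)
  expect_equal(X[2, 2], -5)                    # d1 = 0: no distortion
})

test_that("s = 0 gives a plain Gaussian with matching moments", {
  spec <- gaussian_component(c(3, -2, 10), c(2, 0.5, 4), 1e5, s = 0)
  set.seed(14)
  X <- sample_distorted_gaussian(spec)
  expect_lt(max(abs(colMeans(X) - spec$mean) / (spec$sd / sqrt(1e5))), 4)
  expect_lt(max(abs(apply(X, 2, sd) / spec$sd - 1)), 0.02)
  cc <- cor(X)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02) # diagonal covariance
})

test_that("the conditional mean of axis k2 grows quadratically in the k1 deviate", {
  spec <- gaussian_component(c(0, 0), c(20, 5), 2e5, k1 = 1, k2 = 2, s = 0.002)
  set.seed(15)
  X <- sample_distorted_gaussian(spec)
  fit <- lm(X[, 2] ~ I(X[, 1]^2))              # X1 = d1 * sd_k1
  expect_equal(unname(coef(fit)[2]), 0.002, tolerance = 0.05)
})

test_that("mixtures are reproducible and labeled by component", {
  specs <- list(gaussian_component(c(0, 0), c(1, 1), 120),
                gaussian_component(c(5, 5), c(1, 1), 80))
  a <- make_mixture(specs, seed = 5)
  b <- make_mixture(specs, seed = 5)
  expect_identical(a, b)
  expect_identical(as.vector(table(a$labels)), c(120L, 80L))
  expect_identical(nrow(a$events), 200L)
  expect_error(make_mixture(list(specs[[1]],
                                 gaussian_component(c(0, 0, 0), c(1, 1, 1), 10))),
               "same dimension")
})

test_that("component specifications round-trip through the key-value format", {
  specs <- simulate_highdim(n = 800, n_components = 2, seed = 20)$specs
  path <- withr::local_tempfile(fileext = ".dcf")
  write_component_specs(specs, path)
  back <- read_component_specs(path)
  expect_equal(lapply(specs, unclass), lapply(back, unclass), tolerance = 1e-12)
})

test_that("the shipped high-dimensional component table is valid and in range", {
  path <- system.file("extdata", "synthetic_highdim_components.dcf",
                      package = "contourgate")
  specs <- read_component_specs(path)
  expect_identical(length(specs), 8L)
  for (sp in specs) {
    expect_identical(length(sp$mean), 10L)
    expect_true(all(sp$mean > 0 & sp$mean < 1000))
    expect_true(all(sp$sd > 0 & sp$sd < 200))
    expect_identical(sp$s, 0.004)
    expect_identical(sp$count, 62500L)
  }
})
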