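# The top-down level sweep: peak bookkeeping, merge rules, extraction.

test_that("two tall peaks over a shallow saddle finalize at the last separated level", {
  h <- as_histogram_grid(c(0, 2000, 30, 1000, 0))
  sw <- sweep_levels(h)
  cl <- extract_clusters(NULL, h, sw$final, sw$registry)
  s <- summary(cl)
  expect_identical(nrow(s), 2L)
  expect_equal(s$Lp, c(1999, 999))
  expect_equal(s$Ls, c(29, 29))
  expect_equal(s$C, c(2000, 1000))
  expect_equal(s$bins, c(1L, 1L))             # only the last-separated bins
  expect_equal(s$f, c(0.985, 0.971))
  # both clusters are the level-30 cross sections: bins 2 and 4
  fingerprints <- cluster_fingerprint(h, sw)
  expect_equal(fingerprints[[1]]$bins, 2)
  expect_equal(fingerprints[[2]]$bins, 4)
})

test_that("a retained all-small merge survives to the bottom with full reliability", {
  # Hand-traced: peaks at bins 2 (content 30) and 4 (content 28) merge at
  # level 24 through bin 3 (content 25); both fail the 2-sd rule, the higher
  # is retained, grows to cover bins 2:4 and passes the validity floor.
  h <- as_histogram_grid(c(0, 30, 25, 28, 0))
  sw <- sweep_levels(h)
  cl <- extract_clusters(NULL, h, sw$final, sw$registry)
  s <- summary(cl)
  expect_identical(nrow(s), 1L)
  expect_equal(s$Lp, 29)
  expect_equal(s$Ls, 0)                       # c1 retention leaves no saddle
  expect_equal(s$C, 83)
  expect_equal(s$f, 1)
  expect_equal(cluster_fingerprint(h, sw)[[1]]$bins, 2:4)
})

test_that("peaks below the Poisson validity floor are never finalized", {
  h <- as_histogram_grid(c(0, 5, 1, 4, 0))
  sw <- sweep_levels(h)
  expect_warning(cl <- extract_clusters(NULL, h, sw$final, sw$registry),
                 "eliminated")
  expect_identical(length(cl$clusters), 0L)
})

test_that("an isolated bin is a single never-merged peak", {
  h <- as_histogram_grid(c(0, 0, 40, 0, 0))
  sw <- sweep_levels(h)
  s <- summary(extract_clusters(NULL, h, sw$final, sw$registry))
  expect_equal(s$Lp, 39)                      # level = content - 1
  expect_equal(s$Ls, 0)
  expect_equal(s$C, 40)
  expect_equal(s$f, 1)
})

test_that("fast and exhaustive engines produce bit-identical clusters", {
  set.seed(57)
  for (i in 1:12) {
    h <- random_histogram_2d(side = 9, lambda = 2, npeaks = sample(1:3, 1))
    fast <- sweep_levels(h, engine = "fast")
    naive <- sweep_levels_naive(h)
    expect_identical(cluster_fingerprint(h, fast), cluster_fingerprint(h, naive))
  }
  # and in 1D and 3D
  h1 <- as_histogram_grid(c(3, 40, 12, 25, 2, 31, 30, 1))
  expect_identical(cluster_fingerprint(h1, sweep_levels(h1)),
                   cluster_fingerprint(h1, sweep_levels_naive(h1)))
  set.seed(58)
  cnt <- array(rpois(216, 1), c(6, 6, 6))
  cnt[2, 2, 2] <- 60; cnt[5, 5, 5] <- 45; cnt[2, 5, 3] <- 50
  h3 <- as_histogram_grid(cnt)
  expect_identical(cluster_fingerprint(h3, sweep_levels(h3)),
                   cluster_fingerprint(h3, sweep_levels_naive(h3)))
})

test_that("cross sections nest as the level decreases", {
  set.seed(21)
  h <- random_histogram_2d(side = 8, lambda = 3, npeaks = 2)
  prev <- NULL
  for (L in seq(h$level_max - 1, 0)) {
    cur <- threshold_cross_section(h, L)
    if (!is.null(prev)) {
      expect_true(all(cur[prev == 1] == 1))   # bin sets nest
      lab_cur <- label_aggregates(cur)$labels
      lab_prev <- label_aggregates(prev)$labels
      for (lb in unique(lab_prev[lab_prev > 0])) {
        inside <- lab_cur[lab_prev == lb]     # each aggregate stays in one parent
        expect_identical(length(unique(inside)), 1L)
      }
    }
    prev <- cur
  }
})

test_that("extracted clusters satisfy the structural invariants", {
  set.seed(77)
  mix <- simulate_benchmark_2d(n = 2e4, seed = 77)
  res <- cg_cluster(mix$events)
  s <- summary(res)
  expect_true(all(s$Lp >= s$Ls), TRUE)
  expect_true(all(s$f > 0 & s$f <= 1))
  expect_lte(sum(s$C), res$n)
  # member sets are disjoint and consistent with the assignment vector
  all_members <- unlist(lapply(res$clusters, `[[`, "members"))
  expect_identical(anyDuplicated(all_members), 0L)
  for (rec in res$clusters) {
    expect_identical(length(rec$members), as.integer(rec$C))
    expect_true(all(res$assignment[rec$members] == rec$code))
  }
  expect_identical(sum(res$assignment > 0), length(all_members))
})

test_that("two well-separated populations are recovered with accurate centers", {
  set.seed(19)
  mix <- make_mixture(list(
    gaussian_component(c(0, 0), c(1, 1), 10000),
    gaussian_component(c(8, 8), c(1, 1), 10000)))
  res <- cg_cluster(mix$events)
  expect_identical(length(res$clusters), 2L)
  centers <- do.call(rbind, lapply(res$clusters, `[[`, "center"))
  d <- as.matrix(dist(rbind(c(0, 0), c(8, 8), centers)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), 0.2)       # within 0.2 within-cluster sd
})

test_that("degenerate inputs to the clustering entry point are rejected", {
  expect_error(cg_cluster(matrix(1, 200, 2)), "identical")
  expect_error(cg_cluster(matrix(rnorm(40), ncol = 2)), "at least 100")
  expect_error(cg_cluster(matrix(rnorm(1200), ncol = 6)), "critical_dim")
})
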