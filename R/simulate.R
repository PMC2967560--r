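# Synthetic event data: sums of regular or distorted Gaussian populations.
# A distorted Gaussian couples one axis quadratically onto another: with
# distortion axes k1 and k2 and strength s, an event's k2 coordinate gains
# s * (D1 * sd_k1)^2, where D1 is the same normal deviate that displaced
# axis k1. With s = 0 the component is a plain axis-aligned Gaussian.

#' Standard normal deviates by the Box-Muller transform
#'
#' `sqrt(-2 log(u1)) * cos(2 pi u2)` with `u1`, `u2` uniform on (0, 1). Uses
#' R's uniform stream, so results are reproducible under `set.seed()`.
#'
#' @param n Number of deviates.
#' @param u1,u2 Optional uniforms (for deterministic checks); drawn from
#'   `runif` when omitted.
#' @return Numeric vector of `n` standard normal deviates.
#' @examples
#' box_muller(1, u1 = exp(-2), u2 = 0)  # exactly 2
#' @export
box_muller <- function(n, u1 = NULL, u2 = NULL) {
  if (is.null(u1)) u1 <- stats::runif(n)
  if (is.null(u2)) u2 <- stats::runif(n)
  u1 <- pmax(u1, .Machine$double.xmin)   # guard log(0)
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

#' Specify one (distorted) Gaussian mixture component
#'
#' @param mean Numeric vector of per-axis means.
#' @param sd Positive numeric vector of per-axis standard deviations.
#' @param count Number of events to draw from this component.
#' @param k1,k2 Distinct axis indices: the first and second distortion axes.
#' @param s Non-negative distortion strength; `s = 0` gives a regular
#'   Gaussian. Typical values for intensity-scale data are 0.002-0.004.
#' @return A `component_spec` list.
#' @export
gaussian_component <- function(mean, sd, count, k1 = 1L, k2 = 2L, s = 0) {
  D <- length(mean)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (length(sd) != D) stop("mean and sd must have equal length", call. = FALSE)
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  if (D >= 2L && (k1 == k2 || k1 < 1L || k2 < 1L || k1 > D || k2 > D)) {
    stop("k1 and k2 must be distinct valid axes", call. = FALSE)
  }
  if (s < 0) stop("s must be non-negative", call. = FALSE)
  if (count < 1L) stop("count must be positive", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 count = as.integer(count), k1 = k1, k2 = k2, s = s),
            class = "component_spec")
}

# Pure displacement rule: given the k1-axis deviates d1 (length n) and a
# matrix dmat of independent deviates for the other axes, build the events.
.distort_axes <- function(spec, d1, dmat) {
  D <- length(spec$mean)
  X <- matrix(0, length(d1), D)
  for (k in seq_len(D)) {
    if (D >= 2L && k == spec$k1) {
      X[, k] <- spec$mean[k] + d1 * spec$sd[k]
    } else {
      X[, k] <- spec$mean[k] + dmat[, k] * spec$sd[k]
      if (D >= 2L && k == spec$k2) {
        X[, k] <- X[, k] + spec$s * (d1 * spec$sd[spec$k1])^2
      }
    }
  }
  X
}

#' Draw events from one distorted Gaussian component
#'
#' Per event one deviate is drawn for the first distortion axis and an
#' independent deviate per remaining axis; the second distortion axis gains
#' the quadratic coupling term `s * (D1 * sd_k1)^2`.
#'
#' @param spec A [gaussian_component()].
#' @param n Number of events (defaults to `spec$count`).
#' @return `n x D` numeric matrix.
#' @export
sample_distorted_gaussian <- function(spec, n = spec$count) {
  stopifnot(inherits(spec, "component_spec"))
  D <- length(spec$mean)
  d1 <- box_muller(n)
  dmat <- matrix(box_muller(n * D), n, D)
  .distort_axes(spec, d1, dmat)
}

#' Simulate a mixture of (distorted) Gaussian populations
#'
#' Concatenates the component samples in order and returns the events
#' together with their ground-truth component labels. Fully reproducible
#' from the seed.
#'
#' @param specs List of [gaussian_component()] specifications sharing one
#'   dimension.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return List with `events` (matrix) and `labels` (integer vector,
#'   component index per row).
#' @export
make_mixture <- function(specs, seed = NULL) {
  if (!length(specs)) stop("need at least one component", call. = FALSE)
  Ds <- vapply(specs, function(s) length(s$mean), 0L)
  if (length(unique(Ds)) != 1L) {
    stop("all components must share the same dimension", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(specs, sample_distorted_gaussian)
  events <- do.call(rbind, parts)
  labels <- rep(seq_along(specs), vapply(specs, `[[`, 0L, "count"))
  list(events = events, labels = labels)
}

#' Two-dimensional four-population benchmark
#'
#' Four moderately overlapping distorted Gaussians with pairwise center
#' separations of 3.3-5.0 within-component standard deviations and mixing
#' fractions 0.3/0.3/0.2/0.2 — two close pairs producing high saddles, the
#' geometry typical of fluorescence-intensity data with distinct but
#' touching populations. Optionally adds a fraction of uniform background
#' events (label 0) over the bounding box of the populations.
#'
#' @param n Total number of mixture events (default 1e5).
#' @param s Distortion strength (default 0.002).
#' @param seed Optional seed.
#' @param background Fraction of additional uniform background events
#'   relative to `n` (default 0).
#' @return List with `events`, `labels` (0 = background) and `specs`.
#' @export
simulate_benchmark_2d <- function(n = 1e5, s = 0.002, seed = NULL,
                                  background = 0) {
  fr <- c(0.3, 0.3, 0.2, 0.2)
  cnt <- round(n * fr)
  specs <- list(
    gaussian_component(c(400, 400), c(65, 65), cnt[1], 1, 2, s),
    gaussian_component(c(615, 405), c(70, 70), cnt[2], 1, 2, s),
    gaussian_component(c(405, 615), c(60, 60), cnt[3], 1, 2, s),
    gaussian_component(c(630, 630), c(60, 60), cnt[4], 1, 2, s))
  mix <- make_mixture(specs, seed)
  if (background > 0) {
    nb <- round(n * background)
    lo <- c(400, 400) - 4 * 70; hi <- c(630, 630) + 4 * 70
    bg <- cbind(stats::runif(nb, lo[1], hi[1]), stats::runif(nb, lo[2], hi[2]))
    mix$events <- rbind(mix$events, bg)
    mix$labels <- c(mix$labels, rep(0L, nb))
  }
  mix$specs <- specs
  mix
}

#' Non-convex two-population benchmark
#'
#' A crescent wrapped around a compact blob sitting in its bay: the two are
#' cleanly separated but the crescent is far from convex, probing shape bias
#' of a clustering method. The crescent has a Gaussian angular density along
#' a circular arc (one coherent density mode, as real populations have) and
#' a Gaussian radial spread; a uniform-density ring would instead be a chain
#' of equally tall counting-noise bumps with no dominant mode — a
#' statistically degenerate population rather than a cluster.
#'
#' @param n Total events (75% crescent, 25% blob).
#' @param seed Optional seed.
#' @return List with `events` and `labels` (1 = crescent, 2 = blob).
#' @export
simulate_nonconvex_2d <- function(n = 2e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- round(0.75 * n); n2 <- n - n1
  theta <- 0.9 * box_muller(n1)          # ~2/3 of a turn at 3 sd
  r <- 250 + 30 * box_muller(n1)
  crescent <- cbind(450 + r * cos(theta), 450 + r * sin(theta))
  blob <- cbind(450 + 25 * box_muller(n2), 450 + 25 * box_muller(n2))
  list(events = rbind(crescent, blob), labels = rep(c(1L, 2L), c(n1, n2)))
}

#' High-dimensional distorted-Gaussian benchmark
#'
#' Equal-sized distorted Gaussian components in `D` dimensions with centers
#' drawn uniformly in (0, 1000), per-axis standard deviations uniform in
#' (0, 200), randomly chosen distortion axis pairs and distortion strength
#' `s` (default 0.004) — the standard stress test for the
#' principal-component gating pathway.
#'
#' @param n Total events (default 5e5).
#' @param D Dimension (default 10).
#' @param n_components Number of populations (default 8).
#' @param s Distortion strength.
#' @param seed Optional seed.
#' @return List with `events`, `labels` and `specs` (the generating
#'   components, whose `mean`s are the ground-truth centers).
#' @export
simulate_highdim <- function(n = 5e5, D = 10L, n_components = 8L, s = 0.004,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- rep(floor(n / n_components), n_components)
  cnt[n_components] <- n - sum(cnt[-n_components])
  specs <- vector("list", n_components)
  for (i in seq_len(n_components)) {
    axes <- sample.int(D, 2L)
    specs[[i]] <- gaussian_component(
      mean = stats::runif(D, 0, 1000),
      sd = pmax(stats::runif(D, 0, 200), 1e-6),
      count = cnt[i], k1 = axes[1], k2 = axes[2], s = s)
  }
  mix <- make_mixture(specs)   # seed already applied above
  mix$specs <- specs
  mix
}

#' Read / write component specifications as plain key-value text
#'
#' Components are stored as Debian-control-style records (one block of
#' `field: value` lines per component, blank-line separated) with
#' comma-separated vectors — a plain-text format that round-trips exactly
#' enough for simulation purposes.
#'
#' @param specs List of [gaussian_component()] objects.
#' @param path File path.
#' @return `read_component_specs` returns the list of components;
#'   `write_component_specs` returns `path` invisibly.
#' @export
write_component_specs <- function(specs, path) {
  m <- do.call(rbind, lapply(specs, function(sp) {
    c(mean = paste(sp$mean, collapse = ","),
      sd = paste(sp$sd, collapse = ","),
      count = as.character(sp$count),
      k1 = as.character(sp$k1), k2 = as.character(sp$k2),
      s = as.character(sp$s))
  }))
  write.dcf(m, path)
  invisible(path)
}

#' @rdname write_component_specs
#' @export
read_component_specs <- function(path) {
  m <- read.dcf(path)
  num <- function(x) as.numeric(strsplit(x, ",")[[1]])
  lapply(seq_len(nrow(m)), function(i) {
    gaussian_component(mean = num(m[i, "mean"]), sd = num(m[i, "sd"]),
                       count = as.integer(m[i, "count"]),
                       k1 = as.integer(m[i, "k1"]), k2 = as.integer(m[i, "k2"]),
                       s = as.numeric(m[i, "s"]))
  })
}
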