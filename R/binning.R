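# Optimal equal-per-axis histogram binning.
#
# The bin number N (shared by all axes) is chosen by maximizing a Bayesian
# log posterior over an exhaustive scan; each axis is split into N equal-width
# bins between the column minimum and maximum, the maximum itself falling in
# the last bin so no event is dropped.

# Largest bin-index key that is exactly representable as a double; grids with
# N^D beyond this cannot be addressed reliably.
.KEY_BUDGET <- 2^53

.check_event_matrix <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("event data must be numeric", call. = FALSE)
  if (nrow(data) < 1L || ncol(data) < 1L) {
    stop("event data needs at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("event data contains non-finite values", call. = FALSE)
  }
  data
}

# 0-based per-axis bin indices for every event (n x D integer matrix).
.axis_bins <- function(data, N, lo, hi) {
  n <- nrow(data); D <- ncol(data)
  ix <- matrix(0L, n, D)
  for (d in seq_len(D)) {
    w <- (hi[d] - lo[d]) / N
    if (w > 0) {
      # right-closed bins (lo + (k-1)w, lo + kw], lowest edge in the first
      # bin, upper range edge in the last: no event is ever dropped
      k <- ceiling((data[, d] - lo[d]) / w) - 1
      k[k >= N] <- N - 1
      k[k < 0L] <- 0L
      ix[, d] <- as.integer(k)
    }                         # constant column: every event in bin 0
  }
  ix
}

# Encode 0-based axis indices into 1-based scalar keys (doubles; exact while
# N^D <= 2^53). Axis 1 varies fastest, matching R's column-major linear index.
.encode_bins <- function(ix, N) {
  key <- numeric(nrow(ix))
  mult <- 1
  for (d in seq_len(ncol(ix))) {
    key <- key + as.numeric(ix[, d]) * mult
    mult <- mult * N
  }
  key + 1
}

# Decode 1-based keys back to 1-based axis indices (matrix).
.decode_keys <- function(keys, N, D) {
  k0 <- keys - 1
  out <- matrix(0L, length(keys), D)
  for (d in seq_len(D)) {
    out[, d] <- as.integer(k0 %% N) + 1L
    k0 <- k0 %/% N
  }
  out
}

#' Build an equal-per-axis histogram of an event matrix
#'
#' Splits every channel into `N` equal-width bins between its minimum and
#' maximum and counts the events per D-dimensional bin. Events lying exactly
#' on the upper range edge are assigned to the last bin, so the counts always
#' sum to the number of events. The grid is stored sparsely (occupied bins
#' only), which keeps high-dimensional grids affordable.
#'
#' @param data Numeric matrix, one row per event, one column per channel.
#' @param N Number of bins along each axis (positive integer).
#' @return An object of class `histogram_grid`: a list with elements `N`,
#'   `D`, `lo`, `hi` (per-axis ranges), `keys` (sorted encoded indices of
#'   occupied bins), `counts` (occupied-bin contents), `n` (total events),
#'   `level_max` (largest bin content) and `point_bin` (for each event, the
#'   position of its bin in `keys`).
#' @examples
#' h <- build_histogram(cbind(c(0, 0.5, 1)), 2)
#' h$counts  # 2, 1: the point at the upper edge joins the last bin
#' @export
build_histogram <- function(data, N) {
  data <- .check_event_matrix(data)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer", call. = FALSE)
  D <- ncol(data)
  if (N^D > .KEY_BUDGET) {
    stop("grid capacity exceeded: N^D is too large to address", call. = FALSE)
  }
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  if (any(hi == lo) && N > 1L) {
    warning("constant column(s): treated as a single bin along that axis")
  }
  keys_all <- .encode_bins(.axis_bins(data, N, lo, hi), N)
  keys <- sort(unique(keys_all))
  point_bin <- match(keys_all, keys)
  counts <- tabulate(point_bin, nbins = length(keys))
  structure(
    list(N = N, D = D, lo = lo, hi = hi, keys = keys,
         counts = as.integer(counts), n = nrow(data),
         level_max = max(counts), point_bin = point_bin),
    class = "histogram_grid")
}

#' Construct a histogram grid directly from a dense count array
#'
#' Useful for studying the level sweep on synthetic histograms (for example
#' pure counting-noise grids) without generating event coordinates. All axes
#' must have equal extent. Axis ranges are set to `[0, N]` per axis.
#'
#' @param counts Non-negative integer array (a plain vector is treated as a
#'   one-dimensional grid).
#' @return A `histogram_grid` (with `point_bin = NULL`).
#' @export
as_histogram_grid <- function(counts) {
  dims <- dim(counts)
  if (is.null(dims)) dims <- length(counts)
  if (length(unique(dims)) != 1L) {
    stop("all axes must have the same number of bins", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  N <- dims[1L]; D <- length(dims)
  cnt <- as.integer(counts)
  occ <- which(cnt > 0L)
  structure(
    list(N = N, D = D, lo = rep(0, D), hi = rep(N, D),
         keys = as.numeric(occ), counts = cnt[occ], n = sum(cnt),
         level_max = if (length(occ)) max(cnt[occ]) else 0L,
         point_bin = NULL),
    class = "histogram_grid")
}

#' @export
print.histogram_grid <- function(x, ...) {
  cat(sprintf("histogram_grid: %d^%d grid, %d events in %d occupied bins, max content %d\n",
              x$N, x$D, x$n, length(x$keys), x$level_max))
  invisible(x)
}

# Log posterior from occupied-bin counts (empty bins handled analytically:
# their lgamma(0.5) terms cancel against the -N^D lgamma(0.5) penalty).
.log_posterior_from_counts <- function(n, D, N, counts) {
  Nd <- as.numeric(N)^D
  n * D * log(N) + lgamma(0.5 * Nd) - lgamma(n + 0.5 * Nd) +
    sum(lgamma(counts + 0.5) - lgamma(0.5))
}

#' Bayesian log posterior of an equal-per-axis bin number
#'
#' Evaluates, up to an additive constant, the log posterior probability of
#' using `N` bins per axis for the given events:
#' `n log N^D + log G(N^D/2) - N^D log G(1/2) - log G(n + N^D/2) +
#'  sum_k log G(n_k + 1/2)`, where `G` is the gamma function and `n_k` are
#' the bin contents of `build_histogram(data, N)`. Larger is better.
#'
#' @inheritParams build_histogram
#' @return A single numeric value (log posterior up to a constant; exactly 0
#'   at `N = 1`).
#' @seealso [optimal_bin_number()]
#' @export
log_binning_posterior <- function(data, N) {
  h <- build_histogram(data, N)
  .log_posterior_from_counts(h$n, h$D, h$N, h$counts)
}

#' Select the optimal bin number for an event matrix
#'
#' Exhaustively scans `N = 1..N_max` and returns the bin number maximizing
#' [log_binning_posterior()]; ties are broken toward the smaller `N` and the
#' scan is exhaustive because the posterior can be multimodal. The default
#' `N_max` is `min(200, ceiling(n^(1/D)) + 50)`, comfortably covering the
#' optima seen on event data of this kind.
#'
#' @inheritParams build_histogram
#' @param N_max Upper end of the scan (positive integer).
#' @param details If `TRUE`, return a data frame with the whole posterior
#'   curve (`N`, `log_posterior`) instead of just the argmax.
#' @return The optimal bin number (or the curve when `details = TRUE`, with
#'   the chosen `N` in attribute `"optimal"`).
#' @export
optimal_bin_number <- function(data, N_max = NULL, details = FALSE) {
  data <- .check_event_matrix(data)
  n <- nrow(data); D <- ncol(data)
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  if (all(hi == lo)) {
    warning("all events identical: degenerate histogram, using 1 bin")
    if (details) {
      out <- data.frame(N = 1L, log_posterior = 0)
      attr(out, "optimal") <- 1L
      return(out)
    }
    return(1L)
  }
  if (is.null(N_max)) N_max <- min(200L, as.integer(ceiling(n^(1 / D))) + 50L)
  N_max <- as.integer(N_max)
  if (is.na(N_max) || N_max < 1L) stop("N_max must be a positive integer", call. = FALSE)
  while (N_max^D > .KEY_BUDGET) N_max <- N_max - 1L
  lp <- numeric(N_max)
  for (N in seq_len(N_max)) {
    if (N == 1L) { lp[N] <- 0; next }
    keys_all <- .encode_bins(.axis_bins(data, N, lo, hi), N)
    keys <- unique(keys_all)
    counts <- tabulate(match(keys_all, keys), nbins = length(keys))
    lp[N] <- .log_posterior_from_counts(n, D, N, counts)
  }
  best <- which.max(lp)   # which.max returns the first (smallest N) maximum
  if (details) {
    out <- data.frame(N = seq_len(N_max), log_posterior = lp)
    attr(out, "optimal") <- as.integer(best)
    return(out)
  }
  as.integer(best)
}
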