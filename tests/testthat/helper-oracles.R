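# Independent oracles and fixture builders used across the suite.

# Term-by-term binning posterior, written independently of the package
# internals: dense bin counts via cut()/table over an explicit grid.
oracle_log_posterior <- function(x, N) {
  x <- as.matrix(x)
  n <- nrow(x); D <- ncol(x)
  idx <- rep(0, n)
  for (d in seq_len(D)) {
    lo <- min(x[, d]); hi <- max(x[, d])
    br <- seq(lo, hi, length.out = N + 1)
    k <- as.integer(cut(x[, d], breaks = br, include.lowest = TRUE))
    idx <- idx * N + (k - 1)
  }
  counts <- tabulate(idx + 1, nbins = N^D)
  n * log(N^D) + lgamma(0.5 * N^D) - N^D * lgamma(0.5) -
    lgamma(n + 0.5 * N^D) + sum(lgamma(counts + 0.5))
}

# Moore-connectivity flood fill via igraph: the independent route for
# aggregate labeling. Returns a partition id per nonzero cell (named by
# linear index).
oracle_components <- function(mask) {
  dims <- dim(mask)
  if (is.null(dims)) dims <- length(mask)
  D <- length(dims)
  cells <- which(mask != 0)
  if (!length(cells)) return(integer(0))
  coords <- arrayInd(cells, dims)
  offs <- as.matrix(expand.grid(rep(list(-1:1), D)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  mult <- cumprod(c(1, dims[-D]))
  nonzero <- logical(prod(dims))
  nonzero[cells] <- TRUE
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(offs))) {
    nc <- coords + matrix(offs[j, ], length(cells), D, byrow = TRUE)
    ok <- rep(TRUE, length(cells))
    for (d in seq_len(D)) ok <- ok & nc[, d] >= 1 & nc[, d] <= dims[d]
    lin <- as.integer(1 + (nc[ok, , drop = FALSE] - 1) %*% mult)
    hit <- nonzero[lin]
    from <- c(from, cells[ok][hit])
    to <- c(to, lin[hit])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(from, cells), to = match(to, cells)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(cells)))
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), cells)
}

# Do two labelings induce the same partition of the nonzero cells?
same_partition <- function(lab1, lab2) {
  stopifnot(length(lab1) == length(lab2))
  nz <- lab1 != 0
  if (!identical(nz, lab2 != 0)) return(FALSE)
  a <- lab1[nz]; b <- lab2[nz]
  pairs <- unique(paste(a, b))
  length(pairs) == length(unique(a)) && length(pairs) == length(unique(b))
}

# Random sparse peak-bearing histogram for sweep property tests.
random_histogram_2d <- function(side = 10, lambda = 2, npeaks = 2) {
  cnt <- matrix(stats::rpois(side^2, lambda), side, side)
  for (p in seq_len(npeaks)) {
    cx <- sample.int(side - 2, 1) + 1
    cy <- sample.int(side - 2, 1) + 1
    amp <- sample(30:120, 1)
    for (dx in -1:1) for (dy in -1:1) {
      cnt[cx + dx, cy + dy] <- cnt[cx + dx, cy + dy] +
        round(amp * exp(-(dx^2 + dy^2)))
    }
  }
  as_histogram_grid(cnt)
}

# Compact cluster fingerprint for engine-equivalence comparisons.
cluster_fingerprint <- function(hist, sw) {
  codes <- sw$registry$code[sw$registry$finalized]
  out <- lapply(codes, function(cd) {
    idx <- which(sw$final == cd)
    list(bins = sort(hist$keys[idx]),
         Lp = sw$registry$top_level[cd],
         Ls = sw$registry$saddle_level[cd])
  })
  out[order(vapply(out, function(x) x$bins[1], 0))]
}
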