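# Major vs. small peaks. Bin contents are binomial counts; once the local
# mean content is at least 10 the Poisson limit applies, so the counting
# fluctuation of a bin is estimated by the square root of the average
# content over the bin and its face-adjacent neighbors. A peak rising above
# its saddle by more than twice the combined fluctuation is a genuine
# (major) population; anything else is noise riding on the histogram.

#' Local mean bin content around one bin
#'
#' Arithmetic mean of a bin's content and the contents of its face-adjacent
#' neighbors (one step along a single axis). Neighbors outside the grid are
#' skipped, so boundary bins average over fewer terms; empty in-grid
#' neighbors contribute zero.
#'
#' @param hist A [build_histogram()] result.
#' @param bin Integer vector of length `D`: 1-based bin coordinates.
#' @return The local mean content (non-negative number).
#' @examples
#' h <- as_histogram_grid(c(0, 2000, 30, 1000, 0))
#' local_mean(h, 3)  # (2000 + 30 + 1000) / 3
#' @export
local_mean <- function(hist, bin) {
  stopifnot(inherits(hist, "histogram_grid"))
  bin <- as.integer(bin)
  if (length(bin) != hist$D || anyNA(bin) || any(bin < 1L) || any(bin > hist$N)) {
    stop("bin must be a length-D vector of indices inside the grid", call. = FALSE)
  }
  offs <- .face_offsets(hist$D)
  at <- rbind(bin, sweep(offs, 2, bin, "+"))
  keep <- apply(at, 1, function(v) all(v >= 1L & v <= hist$N))
  at <- at[keep, , drop = FALSE]
  keys <- .encode_bins(at - 1L, hist$N)
  j <- match(keys, hist$keys)
  contents <- ifelse(is.na(j), 0, hist$counts[j])
  mean(contents)
}

# Local means for every occupied bin at once (vector aligned with
# hist$keys). Empty in-grid neighbors count in the denominator with content
# zero, exactly as local_mean().
.local_means <- function(hist) {
  B <- length(hist$keys)
  coords <- .decode_keys(hist$keys, hist$N, hist$D)
  s <- as.numeric(hist$counts)
  denom <- rep(1, B)
  offs <- .face_offsets(hist$D)
  for (j in seq_len(nrow(offs))) {
    nc <- coords + matrix(offs[j, ], B, hist$D, byrow = TRUE)
    ok <- rep(TRUE, B)
    for (d in seq_len(hist$D)) ok <- ok & nc[, d] >= 1L & nc[, d] <= hist$N
    denom[ok] <- denom[ok] + 1
    idx <- which(ok)
    hit <- match(.encode_bins(nc[idx, , drop = FALSE] - 1L, hist$N), hist$keys)
    got <- !is.na(hit)
    s[idx[got]] <- s[idx[got]] + hist$counts[hit[got]]
  }
  s / denom
}

#' Decide whether a peak is major or small
#'
#' A peak of top level `Lp` merging at saddle level `Ls` is major when the
#' Poisson approximation is valid at its top (`b_bar_p >= 10`) and its
#' height above the saddle exceeds twice the combined counting fluctuation:
#' `Lp - Ls > 2 * sqrt(b_bar_p + b_bar_s)`. When `b_bar_p < 10` the Poisson
#' limit of the binomial bin-content distribution fails and the peak is
#' always considered small.
#'
#' @param Lp Peak top level (integer, `Lp >= Ls`).
#' @param Ls Saddle level (non-negative integer).
#' @param b_bar_p Local mean content at the peak top bin.
#' @param b_bar_s Local mean content at the saddle bin.
#' @return `TRUE` for a major peak, `FALSE` for a small one.
#' @examples
#' is_major_peak(999, 29, 343.3, 1010)  # TRUE: 970 > 2 * sqrt(1353.3)
#' is_major_peak(999, 29, 5, 1010)      # FALSE: Poisson approximation fails
#' @export
is_major_peak <- function(Lp, Ls, b_bar_p, b_bar_s) {
  if (anyNA(c(Lp, Ls, b_bar_p, b_bar_s)) || b_bar_p < 0 || b_bar_s < 0 ||
      Ls < 0 || Lp < Ls) {
    stop("need Lp >= Ls >= 0 and non-negative local means", call. = FALSE)
  }
  b_bar_p >= 10 && (Lp - Ls) > 2 * sqrt(b_bar_p + b_bar_s)
}

#' Reliability of a cluster assignment
#'
#' The fraction of a peak's height that stands clear of its saddle:
#' `f = (Lp - Ls) / Lp`. A peak that never coalesced with another retained
#' peak has `Ls = 0` and `f = 1`; strongly overlapping populations have
#' small `f`.
#'
#' @param Lp Peak top level (positive).
#' @param Ls Saddle level (`0 <= Ls <= Lp`).
#' @return Numeric in `(0, 1]`, vectorized over its arguments.
#' @examples
#' cluster_reliability(3385, 756)  # 0.777 to three decimals
#' @export
cluster_reliability <- function(Lp, Ls) {
  if (anyNA(Lp) || anyNA(Ls) || any(Lp < 1) || any(Ls < 0) || any(Ls > Lp)) {
    stop("need Lp >= Ls >= 0 and Lp >= 1", call. = FALSE)
  }
  (Lp - Ls) / Lp
}
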