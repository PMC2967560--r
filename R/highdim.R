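# Data wider than the critical dimension are projected onto the leading
# principal components before gating: histogram size, run time and the
# events needed for an adequate histogram all grow super-linearly with
# dimension, while the populations' separation is usually carried by a few
# directions of large variance. Memberships found in the subspace are
# mapped straight back to the original rows.

#' Principal-component basis for projecting wide event data
#'
#' Eigendecomposition of the data covariance matrix, truncated to the
#' `target_dim` leading components. Each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive, making the basis reproducible.
#'
#' @param data Numeric event matrix with more columns than `target_dim` and
#'   more rows than columns.
#' @param target_dim Number of components to keep (default 5).
#' @return Object of class `projection_basis`: `mean` (column means), `axes`
#'   (`D x target_dim` orthonormal matrix), `eigenvalues` (non-increasing),
#'   and `prop_var` (fraction of total variance retained — a diagnostic for
#'   how much separation the projection can preserve).
#' @export
pca_basis <- function(data, target_dim = 5L) {
  data <- .check_event_matrix(data)
  D <- ncol(data)
  target_dim <- as.integer(target_dim)
  if (D <= target_dim) stop("data dimension must exceed target_dim", call. = FALSE)
  if (nrow(data) <= D) stop("need more events than dimensions", call. = FALSE)
  e <- eigen(stats::cov(data), symmetric = TRUE)
  vals <- e$values
  if (sum(vals > max(vals) * 1e-12) < target_dim) {
    warning("fewer than target_dim non-degenerate principal axes; ",
            "zero-variance axes retained")
  }
  axes <- e$vectors[, seq_len(target_dim), drop = FALSE]
  for (j in seq_len(target_dim)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  structure(list(mean = colMeans(data), axes = axes,
                 eigenvalues = pmax(vals[seq_len(target_dim)], 0),
                 prop_var = sum(pmax(vals[seq_len(target_dim)], 0)) /
                   sum(pmax(vals, 0))),
            class = "projection_basis")
}

#' Project events onto a principal-component basis
#'
#' @param data Event matrix with the same columns the basis was fitted on.
#' @param basis A [pca_basis()] result.
#' @return `n x target_dim` matrix of component scores.
#' @export
project_events <- function(data, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  data <- .check_event_matrix(data)
  sweep(data, 2, basis$mean) %*% basis$axes
}

#' Cluster event data of any dimension
#'
#' For data up to `critical_dim` columns this is exactly [cg_cluster()]. For
#' wider data the events are projected onto the `critical_dim` leading
#' principal components, gated there, and every recovered population's
#' member rows are carried back to the original space: population sizes are
#' unchanged, and cluster centers are recomputed as per-coordinate means of
#' the members in the full-dimensional space. Note that the projection can
#' merge populations that were separated only in the discarded directions;
#' `$basis$prop_var` reports how much variance the subspace retains.
#'
#' @inheritParams cg_cluster
#' @param critical_dim Largest dimension gated directly (default 5).
#' @param ... Passed on to [cg_cluster()] (e.g. `bins`, `N_max`).
#' @return A `cg_clusters` object; for projected runs the grid and bins
#'   refer to the subspace, while `members`, `assignment` and `center` refer
#'   to the original rows and coordinates, and `$basis` holds the
#'   [pca_basis()].
#' @export
cluster_high_dimensional <- function(data, critical_dim = 5L, ...) {
  data <- .check_event_matrix(data)
  if (ncol(data) <= critical_dim) {
    return(cg_cluster(data, critical_dim = critical_dim, ...))
  }
  basis <- pca_basis(data, target_dim = critical_dim)
  proj <- project_events(data, basis)
  res <- cg_cluster(proj, critical_dim = critical_dim, ...)
  for (i in seq_along(res$clusters)) {
    rows <- res$clusters[[i]]$members
    res$clusters[[i]]$center <- colMeans(data[rows, , drop = FALSE])
  }
  res$basis <- basis
  res
}
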