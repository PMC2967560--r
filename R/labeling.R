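# Percolation-style labeling of bin aggregates in one histogram cross
# section. A cross section marks every bin whose content strictly exceeds a
# level; aggregates are diagonally connected (Moore) components of the mark.
# The labeling is the classic three-step lattice routine: initialize, raster
# scan resolving labels through an equivalence vector, then a second scan
# replacing each label by its root. Including the next-nearest (diagonal)
# predecessors in the scan is what keeps elongated slanted aggregates whole.

.moore_offsets <- function(D) {
  g <- as.matrix(expand.grid(rep(list(-1:1), D)))
  dimnames(g) <- NULL
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

# Offsets pointing at already-scanned cells: the highest-axis nonzero
# component is negative. For grids with side >= 2 this equals "smaller
# linear index", i.e. the causal half of the Moore neighborhood.
.causal_offsets <- function(D) {
  off <- .moore_offsets(D)
  lead <- apply(off, 1, function(v) v[max(which(v != 0L))])
  off[lead < 0L, , drop = FALSE]
}

# +/- 1 along single axes (face neighbors, used by local means).
.face_offsets <- function(D) {
  rbind(diag(1L, D), diag(-1L, D))
}

#' Threshold one cross section of a histogram
#'
#' Marks each bin of the grid with 1 when its content strictly exceeds
#' `level`, else 0. At `level = level_max` the section is empty.
#'
#' @param hist A [build_histogram()] result.
#' @param level Integer in `[0, level_max]`.
#' @return Integer array with `dim = rep(N, D)` (a vector for 1D grids).
#' @export
threshold_cross_section <- function(hist, level) {
  stopifnot(inherits(hist, "histogram_grid"))
  if (length(level) != 1L || is.na(level) || level < 0 || level > hist$level_max) {
    stop("level must lie in [0, level_max]", call. = FALSE)
  }
  total <- hist$N^hist$D
  if (total > 2e7) {
    stop("grid too large to materialize densely", call. = FALSE)
  }
  arr <- array(0L, rep(hist$N, hist$D))
  arr[hist$keys] <- as.integer(hist$counts > level)
  arr
}

#' Label the bin aggregates of a binary cross section
#'
#' Assigns one positive integer per diagonally-connected (Moore) aggregate of
#' nonzero cells, via the three-step procedure: provisional labels are created
#' in raster-scan order whenever a cell has no previously-scanned nonzero
#' neighbor; otherwise the cell and all its predecessors' labels are pointed
#' at the smallest involved root through the equivalence vector; a second
#' scan replaces every provisional label by its root. Consequently each
#' aggregate ends up carrying the smallest label ever created inside it.
#'
#' @param mask Numeric/integer/logical array (any dimension); nonzero means
#'   "in the cross section". A plain vector is treated as a 1D grid.
#' @return A list: `labels` (array like `mask`, 0 outside aggregates),
#'   `provisional` (labels after the first scan), `count_map` (the label
#'   equivalence vector), `max_label` (number of labels created) and
#'   `n_aggregates`.
#' @examples
#' m <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
#' label_aggregates(m)$n_aggregates  # 1: the diagonal predecessors join it
#' @export
label_aggregates <- function(mask) {
  dims <- dim(mask)
  if (is.null(dims)) dims <- length(mask)
  D <- length(dims)
  total <- prod(dims)
  labels <- integer(total)
  prov <- integer(total)
  cells <- which(mask != 0)
  if (!length(cells)) {
    return(list(labels = array(labels, dims), provisional = array(prov, dims),
                count_map = integer(0), max_label = 0L, n_aggregates = 0L))
  }
  coords <- arrayInd(cells, dims)
  offs <- .causal_offsets(D)
  mult <- cumprod(c(1, dims[-D]))
  nonzero <- logical(total)
  nonzero[cells] <- TRUE
  # neighbor cell index per (cell, causal offset); NA when out of grid or zero
  nb <- matrix(NA_integer_, length(cells), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    nc <- coords + matrix(offs[j, ], length(cells), D, byrow = TRUE)
    ok <- rep(TRUE, length(cells))
    for (d in seq_len(D)) ok <- ok & nc[, d] >= 1L & nc[, d] <= dims[d]
    lin <- as.integer(1 + (nc[ok, , drop = FALSE] - 1) %*% mult)
    lin[!nonzero[lin]] <- NA_integer_
    nb[ok, j] <- lin
  }
  parent <- integer(0)
  il <- 0L
  for (i in seq_along(cells)) {          # cells are in increasing scan order
    labs <- labels[nb[i, ]]
    labs <- labs[!is.na(labs)]
    if (!length(labs)) {
      il <- il + 1L
      parent[il] <- il
      lab <- il
    } else {
      roots <- integer(length(labs))
      for (k in seq_along(labs)) {
        r <- labs[k]
        while (parent[r] != r) { parent[r] <- parent[parent[r]]; r <- parent[r] }
        roots[k] <- r
      }
      lab <- min(roots)
      parent[roots] <- lab
    }
    labels[cells[i]] <- lab
    prov[cells[i]] <- lab
  }
  # second scan: replace by roots
  root_of <- seq_len(il)
  for (r in seq_len(il)) {
    x <- r
    while (parent[x] != x) x <- parent[x]
    root_of[r] <- x
  }
  labels[cells] <- root_of[labels[cells]]
  list(labels = array(labels, dims), provisional = array(prov, dims),
       count_map = parent, max_label = il,
       n_aggregates = length(unique(root_of)))
}

#' Resolve a provisional aggregate label to its root
#'
#' Follows the equivalence vector until it reaches a fixed point — the
#' smallest label of the aggregate.
#'
#' @param label Positive integer indexing `count_map`.
#' @param count_map Integer equivalence vector whose chains end in fixed
#'   points.
#' @return The root label.
#' @examples
#' resolve_label(3, c(1, 1, 2))  # 3 -> 2 -> 1
#' @export
resolve_label <- function(label, count_map) {
  if (length(label) != 1L || is.na(label) || label < 1L || label > length(count_map)) {
    stop("label must index count_map", call. = FALSE)
  }
  count_map <- as.integer(count_map)
  x <- as.integer(label)
  for (step in seq_len(length(count_map) + 1L)) {
    nxt <- count_map[x]
    if (is.na(nxt) || nxt < 1L || nxt > length(count_map)) {
      stop("count_map chain leaves the vector", call. = FALSE)
    }
    if (nxt == x) return(x)
    x <- nxt
  }
  stop("count_map chain does not terminate in a fixed point", call. = FALSE)
}
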