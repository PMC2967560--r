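# Top-down level sweep. Cross sections of the histogram are taken at every
# level from level_max-1 down to 0 ("content > LEVEL", so there are
# level_max sections). Walking downward, each section's aggregates are
# compared with the previous section's: a fresh aggregate registers a new
# peak; an aggregate holding one known peak just grows; when aggregates
# carrying several peaks coalesce, the significance rule decides which peaks
# are genuine populations. A major peak's aggregate from one level above the
# merge — its largest still-separated cross section — is frozen into the
# final label grid; small peaks are eliminated. Peaks that never coalesce
# keep their full bottom aggregate.
#
# The fast engine never rebuilds a cross section: occupied bins activate in
# decreasing content order (a bin enters at level content-1) and an
# incremental union-find with O(1) member-list concatenation maintains the
# aggregates, which is O(B log B) in the number of occupied bins plus the
# actual set-change work. A dense per-integer-level engine with identical
# semantics is kept as `sweep_levels_naive` and is asserted bit-identical in
# the tests.

# Edges between occupied Moore-adjacent bins. Columns a, b are positions in
# hist$keys; an edge is present in the cross section at levels
# < min(content a, content b), i.e. it activates at level min(count) - 1.
.adjacency_edges <- function(hist) {
  B <- length(hist$keys)
  coords <- .decode_keys(hist$keys, hist$N, hist$D)
  offs <- .moore_offsets(hist$D)
  lead <- apply(offs, 1, function(v) v[max(which(v != 0L))])
  offs <- offs[lead > 0L, , drop = FALSE]   # one direction per pair
  ea <- vector("list", nrow(offs))
  eb <- vector("list", nrow(offs))
  for (j in seq_len(nrow(offs))) {
    nc <- coords + matrix(offs[j, ], B, hist$D, byrow = TRUE)
    ok <- rep(TRUE, B)
    for (d in seq_len(hist$D)) ok <- ok & nc[, d] >= 1L & nc[, d] <= hist$N
    idx <- which(ok)
    hit <- match(.encode_bins(nc[idx, , drop = FALSE] - 1L, hist$N), hist$keys)
    got <- !is.na(hit)
    ea[[j]] <- idx[got]
    eb[[j]] <- hit[got]
  }
  cbind(a = unlist(ea), b = unlist(eb))
}

# The merge rule applied when an aggregate holds >= 2 known peaks.
# codes/tops/ptypes describe those peaks (ptype 1 single, -1 merged major),
# bbp their local means at the characteristic bins, bbs the local mean at
# the saddle (bridging) bin, level the merge level. Returns the action per
# peak: "keep" (still tracked, unchanged), "retain" (c1 winner),
# "eliminate" (small, dropped), "promote" (single major -> merged major,
# its previous-level aggregate is finalized).
.peak_merge_decision <- function(codes, tops, ptypes, bbp, bbs, level) {
  single <- ptypes == 1L
  INEW <- sum(single)
  major <- single & bbp >= 10 & (tops - level) > 2 * sqrt(bbp + bbs)
  IHIGH <- sum(major)
  action <- rep("keep", length(codes))
  if (INEW == length(codes) && IHIGH <= 1L) {
    # c1: every peak was single and at most one is major -> keep only the
    # highest (ties to the smallest code); typical of a major peak whose
    # flanks produce transient small aggregates.
    win <- order(-tops, codes)[1L]
    action[] <- "eliminate"
    action[win] <- "retain"
  } else {
    action[single & major] <- "promote"
    action[single & !major] <- "eliminate"
  }
  action
}

#' Sweep the histogram cross sections from the top down
#'
#' Runs the full level sweep and returns the peak registry together with the
#' final label grid holding every finalized population's largest
#' still-separated aggregate. A surviving single peak (one that never
#' coalesced with a retained peak) is finalized with its bottom-level
#' aggregate, provided the local mean content at its top reaches the
#' Poisson-validity floor of 10 — below that the peak is indistinguishable
#' from a counting fluctuation and is dropped.
#'
#' @param hist A [build_histogram()] or [as_histogram_grid()] result with
#'   `level_max >= 1`.
#' @param engine `"fast"` (incremental, default) or `"exhaustive"` (dense
#'   relabeling at every integer level; identical output, small grids only).
#' @return A list with `registry` (data frame: `code`, `key`,
#'   `top_level`, `saddle_level`, `ptype`, `finalized`), `final` (integer
#'   vector aligned with `hist$keys`; 0 = unclustered bin) and `events`
#'   (emergence / elimination / merge log).
#' @export
sweep_levels <- function(hist, engine = c("fast", "exhaustive")) {
  stopifnot(inherits(hist, "histogram_grid"))
  engine <- match.arg(engine)
  if (hist$level_max < 1L) stop("histogram is empty", call. = FALSE)
  if (engine == "fast") .sweep_fast(hist) else sweep_levels_naive(hist)
}

.sweep_fast <- function(hist) {
  B <- length(hist$keys)
  counts <- hist$counts
  lm <- .local_means(hist)
  edges <- .adjacency_edges(hist)
  ne <- nrow(edges)
  if (ne) {
    ea <- edges[, 1L]; eb <- edges[, 2L]
    elev <- pmin(counts[ea], counts[eb]) - 1L
    oe <- order(elev, decreasing = TRUE)
    ea <- ea[oe]; eb <- eb[oe]; elev <- elev[oe]
  } else {
    ea <- eb <- elev <- integer(0)
  }
  activation <- counts - 1L
  ob <- order(activation, decreasing = TRUE)
  levels_desc <- sort(unique(activation), decreasing = TRUE)

  parent <- integer(B)          # 0 = not yet active
  sz <- integer(B)
  head <- integer(B); tail <- integer(B); nxt <- integer(B)
  cons <- vector("list", B)     # per-level constituents of freshly merged roots
  root_peaks <- vector("list", B)
  final <- integer(B)

  code_cap <- 64L
  top <- integer(code_cap); saddle <- integer(code_cap)
  ptype <- integer(code_cap); fin <- logical(code_cap)
  char_idx <- integer(code_cap)
  ncl <- 0L
  ev <- list(); nev <- 0L
  log_ev <- function(level, what, code, detail = NA_integer_) {
    nev <<- nev + 1L
    ev[[nev]] <<- list(level = level, event = what, code = code, detail = detail)
  }

  bi <- 1L; ei <- 1L
  for (L in levels_desc) {
    b2 <- bi
    while (b2 <= B && activation[ob[b2]] == L) b2 <- b2 + 1L
    newbins <- ob[seq.int(bi, b2 - 1L)]
    bi <- b2
    parent[newbins] <- newbins; sz[newbins] <- 1L
    head[newbins] <- newbins; tail[newbins] <- newbins; nxt[newbins] <- 0L
    e2 <- ei
    while (e2 <= ne && elev[e2] == L) e2 <- e2 + 1L
    touched <- integer(e2 - ei)
    ntc <- 0L
    while (ei <= ne && elev[ei] == L) {
      a <- ea[ei]; b <- eb[ei]; ei <- ei + 1L
      ra <- a
      while (parent[ra] != ra) { parent[ra] <- parent[parent[ra]]; ra <- parent[ra] }
      rb <- b
      while (parent[rb] != rb) { parent[rb] <- parent[parent[rb]]; rb <- parent[rb] }
      if (ra == rb) next
      if (sz[ra] < sz[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      ua <- cons[[ra]]; if (is.null(ua)) ua <- ra
      ub <- cons[[rb]]; if (is.null(ub)) ub <- rb
      parent[rb] <- ra
      sz[ra] <- sz[ra] + sz[rb]
      cons[[ra]] <- c(ua, ub)
      cons[rb] <- list(NULL)
      ntc <- ntc + 1L
      touched[ntc] <- ra
    }
    # current roots of every unit touched this level
    groups <- newbins
    if (ntc) groups <- c(groups, touched[seq_len(ntc)])
    if (!length(groups)) next
    for (k in seq_along(groups)) {
      g <- groups[k]
      while (parent[g] != g) g <- parent[g]
      groups[k] <- g
    }
    groups <- unique(groups)
    for (g in groups) {
      units <- cons[[g]]
      if (is.null(units)) units <- g
      old_units <- units[counts[units] > L + 1L]
      new_units <- units[counts[units] == L + 1L]
      if (!length(old_units)) {
        # case a: a peak is just emerging
        ncl <- ncl + 1L
        if (ncl > code_cap) {
          code_cap <- code_cap * 2L
          length(top) <- code_cap; length(saddle) <- code_cap
          length(ptype) <- code_cap; length(fin) <- code_cap
          length(char_idx) <- code_cap
          top[is.na(top)] <- 0L; saddle[is.na(saddle)] <- 0L
          ptype[is.na(ptype)] <- 0L; fin[is.na(fin)] <- FALSE
          char_idx[is.na(char_idx)] <- 0L
        }
        char_idx[ncl] <- min(units)      # keys are sorted: lexicographically first bin
        top[ncl] <- L; saddle[ncl] <- 0L
        ptype[ncl] <- 1L; fin[ncl] <- FALSE
        keep_codes <- ncl
        log_ev(L, "emerge", ncl)
      } else if (length(old_units) == 1L) {
        # case b (or growth of an already-merged aggregate): nothing changes
        keep_codes <- root_peaks[[old_units]]
      } else {
        # case c: aggregates carrying several peaks coalesce at this level
        plists <- lapply(old_units, function(u) root_peaks[[u]])
        codes <- unlist(plists)
        owners <- rep(old_units, lengths(plists))
        sbin <- min(new_units)           # bridging bins all hold L+1 events
        bbs <- lm[sbin]
        act <- .peak_merge_decision(codes, top[codes], ptype[codes],
                                    lm[char_idx[codes]], bbs, L)
        keep_codes <- codes[act %in% c("keep", "retain")]
        for (k in which(act == "eliminate")) {
          cd <- codes[k]
          ptype[cd] <- 0L; saddle[cd] <- L
          log_ev(L, "eliminate", cd, sbin)
        }
        for (k in which(act == "promote")) {
          cd <- codes[k]
          ptype[cd] <- -1L; saddle[cd] <- L; fin[cd] <- TRUE
          cur <- head[owners[k]]         # previous-level aggregate, still intact
          while (cur != 0L) { final[cur] <- cd; cur <- nxt[cur] }
          keep_codes <- c(keep_codes, cd)
          log_ev(L, "finalize_merge", cd, sbin)
        }
      }
      # concatenate member lists of all units into the new root
      ph <- 0L; pt <- 0L
      for (u in units) {
        if (head[u] == 0L) next
        if (ph == 0L) ph <- head[u] else nxt[pt] <- head[u]
        pt <- tail[u]
        if (u != g) { head[u] <- 0L; tail[u] <- 0L }
      }
      head[g] <- ph; tail[g] <- pt
      for (u in units) if (u != g) root_peaks[u] <- list(NULL)
      root_peaks[[g]] <- keep_codes
      cons[g] <- list(NULL)
    }
  }
  # bottom of the sweep: finalize surviving single peaks above the
  # Poisson-validity floor
  act <- which(parent > 0L)
  r <- act
  repeat {
    r2 <- parent[r]
    if (identical(r2, r)) break
    r <- r2
  }
  for (rt in unique(r)) {
    for (cd in root_peaks[[rt]]) {
      if (ptype[cd] != 1L) next
      if (lm[char_idx[cd]] >= 10) {
        fin[cd] <- TRUE
        cur <- head[rt]
        while (cur != 0L) { final[cur] <- cd; cur <- nxt[cur] }
        log_ev(0L, "finalize_survivor", cd)
      } else {
        ptype[cd] <- 0L
        log_ev(0L, "drop_small_survivor", cd)
      }
    }
  }
  registry <- data.frame(
    code = seq_len(ncl),
    key = hist$keys[char_idx[seq_len(ncl)]],
    top_level = top[seq_len(ncl)],
    saddle_level = saddle[seq_len(ncl)],
    ptype = ptype[seq_len(ncl)],
    finalized = fin[seq_len(ncl)])
  events <- if (nev) {
    data.frame(level = vapply(ev, `[[`, 0L, "level"),
               event = vapply(ev, `[[`, "", "event"),
               code = vapply(ev, `[[`, 0L, "code"),
               detail = vapply(ev, `[[`, 0L, "detail"))
  } else {
    data.frame(level = integer(0), event = character(0),
               code = integer(0), detail = integer(0))
  }
  list(registry = registry, final = final, events = events)
}

#' Exhaustive reference sweep (dense relabeling at every integer level)
#'
#' Semantically identical to the fast engine of [sweep_levels()] but
#' rebuilds and relabels the full cross section at every integer level from
#' `level_max - 1` down to 0. Intended for verification on small grids.
#'
#' @inheritParams sweep_levels
#' @return Same structure as [sweep_levels()] (without an event log).
#' @export
sweep_levels_naive <- function(hist) {
  stopifnot(inherits(hist, "histogram_grid"))
  total <- hist$N^hist$D
  if (total > 2e6) stop("grid too large for the exhaustive engine", call. = FALSE)
  cnt <- array(0L, rep(hist$N, hist$D))
  cnt[hist$keys] <- hist$counts
  lmv <- numeric(total)
  lmv[hist$keys] <- .local_means(hist)

  top <- integer(0); saddle <- integer(0); ptype <- integer(0)
  fin <- logical(0); char_cell <- integer(0)
  tracked <- integer(0)
  final <- integer(total)
  prev_lab <- array(0L, rep(hist$N, hist$D))
  prev_active <- array(FALSE, rep(hist$N, hist$D))
  lab <- NULL
  for (L in seq(hist$level_max - 1L, 0L)) {
    mask <- cnt > L
    lab <- label_aggregates(mask)$labels
    tr0 <- tracked                       # peaks known entering this level
    agg_of <- lab[char_cell[tr0]]
    all_labs <- sort(unique(lab[lab > 0L]))
    for (lb in all_labs) {
      codes <- tr0[agg_of == lb]
      if (!length(codes)) {
        cells <- which(lab == lb)
        ncl <- length(top) + 1L
        top[ncl] <- L; saddle[ncl] <- 0L; ptype[ncl] <- 1L
        fin[ncl] <- FALSE; char_cell[ncl] <- min(cells)
        tracked <- c(tracked, ncl)
      } else if (length(codes) >= 2L) {
        cells <- which(lab == lb)
        bridging <- cells[!prev_active[cells]]
        if (!length(bridging)) next  # aggregate unchanged since the previous level
        sbin <- min(bridging)
        act <- .peak_merge_decision(codes, top[codes], ptype[codes],
                                    lmv[char_cell[codes]], lmv[sbin], L)
        for (k in seq_along(codes)) {
          cd <- codes[k]
          if (act[k] == "eliminate") {
            ptype[cd] <- 0L; saddle[cd] <- L
            tracked <- setdiff(tracked, cd)
          } else if (act[k] == "promote") {
            ptype[cd] <- -1L; saddle[cd] <- L; fin[cd] <- TRUE
            prevcells <- which(prev_lab == prev_lab[char_cell[cd]])
            final[prevcells] <- cd
          }
        }
      }
    }
    prev_lab <- lab
    prev_active <- mask
  }
  for (cd in tracked) {
    if (ptype[cd] != 1L) next
    if (lmv[char_cell[cd]] >= 10) {
      fin[cd] <- TRUE
      final[which(lab == lab[char_cell[cd]])] <- cd
    } else {
      ptype[cd] <- 0L
    }
  }
  registry <- data.frame(
    code = seq_along(top), key = as.numeric(char_cell),
    top_level = top, saddle_level = saddle, ptype = ptype, finalized = fin)
  list(registry = registry, final = final[hist$keys],
       events = data.frame(level = integer(0), event = character(0),
                           code = integer(0), detail = integer(0)))
}

#' Extract gated populations from a finished sweep
#'
#' Collects, for every finalized peak, its member bins and events, the peak
#' top level `Lp`, the saddle level `Ls` (0 for a peak that never coalesced
#' with a retained peak), the reliability `f = (Lp - Ls)/Lp` and the
#' per-coordinate mean of the member events. Events in unlabeled bins stay
#' unassigned (code 0): the gating is deliberately tight. Clusters are
#' numbered 1, 2, ... by decreasing population size.
#'
#' @param data The event matrix the histogram was built from (or `NULL` when
#'   the histogram was constructed from counts alone; member rows and
#'   centers are then omitted).
#' @param hist The [build_histogram()] result.
#' @param final Final label vector from [sweep_levels()].
#' @param registry Peak registry from [sweep_levels()].
#' @return An object of class `cg_clusters`: list with `clusters` (one
#'   record per population: `code`, `peak_code`, `Lp`, `Ls`, `f`, `C`,
#'   `n_bins`, `bins`, `members`, `center`), `assignment` (per-event cluster
#'   code, 0 = unassigned) and `n`.
#' @export
extract_clusters <- function(data, hist, final, registry) {
  stopifnot(inherits(hist, "histogram_grid"))
  codes <- registry$code[registry$finalized]
  if (!length(codes)) {
    warning("all peaks were eliminated: empty cluster set")
  }
  recs <- list()
  for (cd in codes) {
    idx <- which(final == cd)
    if (!length(idx)) next
    Lp <- registry$top_level[registry$code == cd]
    Ls <- registry$saddle_level[registry$code == cd]
    members <- NULL; center <- NULL
    if (!is.null(data) && !is.null(hist$point_bin)) {
      members <- which(final[hist$point_bin] == cd)
      center <- colMeans(data[members, , drop = FALSE])
    }
    recs[[length(recs) + 1L]] <- list(
      code = NA_integer_, peak_code = cd,
      Lp = Lp, Ls = Ls, f = cluster_reliability(Lp, Ls),
      C = sum(hist$counts[idx]), n_bins = length(idx),
      bins = .decode_keys(hist$keys[idx], hist$N, hist$D),
      members = members, center = center)
  }
  if (length(recs)) {
    ord <- order(-vapply(recs, `[[`, 0, "C"),
                 vapply(recs, `[[`, 0, "peak_code"))
    recs <- recs[ord]
    for (i in seq_along(recs)) recs[[i]]$code <- i
  }
  assignment <- NULL
  if (!is.null(data) && !is.null(hist$point_bin)) {
    assignment <- integer(hist$n)
    for (rec in recs) assignment[rec$members] <- rec$code
  }
  structure(list(clusters = recs, assignment = assignment, n = hist$n,
                 N = hist$N, D = hist$D, level_max = hist$level_max),
            class = "cg_clusters")
}

#' @export
print.cg_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) from %d events on a %d^%d grid (max content %d)\n",
              length(x$clusters), x$n, x$N, x$D, x$level_max))
  if (length(x$clusters)) {
    print(summary(x), row.names = FALSE)
    assigned <- sum(vapply(x$clusters, `[[`, 0, "C"))
    cat(sprintf("assigned: %d / %d events (%.1f%%)\n",
                assigned, x$n, 100 * assigned / x$n))
  }
  invisible(x)
}

#' @export
summary.cg_clusters <- function(object, ...) {
  recs <- object$clusters
  df <- data.frame(
    code = vapply(recs, `[[`, 0L, "code"),
    Lp = vapply(recs, `[[`, 0, "Lp"),
    Ls = vapply(recs, `[[`, 0, "Ls"),
    C = vapply(recs, `[[`, 0, "C"),
    bins = vapply(recs, `[[`, 0L, "n_bins"),
    f = round(vapply(recs, `[[`, 0, "f"), 3))
  cent <- lapply(recs, `[[`, "center")
  if (length(cent) && !is.null(cent[[1L]])) {
    cm <- do.call(rbind, cent)
    colnames(cm) <- paste0("center_", seq_len(ncol(cm)))
    df <- cbind(df, cm)
  }
  df
}

#' Cluster an event matrix by density-contour gating
#'
#' The main entry point for data of up to `critical_dim` dimensions: selects
#' the optimal bin number (unless `bins` is given), builds the histogram,
#' sweeps its cross sections from the top down and extracts the gated
#' populations. Deterministic given the data and options.
#'
#' @param data Numeric event matrix (rows = events, columns = channels).
#' @param bins Optional fixed bin number per axis; default: chosen by
#'   [optimal_bin_number()].
#' @param N_max Scan limit passed to [optimal_bin_number()].
#' @param critical_dim Largest dimension analyzed directly (default 5); for
#'   wider data use [cluster_high_dimensional()].
#' @param min_events Minimum number of events required (default 100): below
#'   this no adequate histogram can be formed.
#' @param engine Sweep engine, see [sweep_levels()].
#' @return A `cg_clusters` object (see [extract_clusters()]); the chosen bin
#'   number is in `$N`.
#' @examples
#' set.seed(1)
#' xy <- rbind(matrix(rnorm(4000), ncol = 2),
#'             matrix(rnorm(4000, mean = 8), ncol = 2))
#' cg_cluster(xy, bins = 15)
#' @export
cg_cluster <- function(data, bins = NULL, N_max = NULL, critical_dim = 5L,
                       min_events = 100L, engine = c("fast", "exhaustive")) {
  data <- .check_event_matrix(data)
  if (ncol(data) > critical_dim) {
    stop("data dimension exceeds critical_dim; use cluster_high_dimensional()",
         call. = FALSE)
  }
  if (nrow(data) < min_events) {
    stop(sprintf("need at least %d events for an adequate histogram", min_events),
         call. = FALSE)
  }
  if (all(apply(data, 2, function(v) v[1L] == v))) {
    stop("all events are identical: no histogram structure", call. = FALSE)
  }
  N <- if (is.null(bins)) optimal_bin_number(data, N_max) else as.integer(bins)
  hist <- build_histogram(data, N)
  sw <- sweep_levels(hist, engine = match.arg(engine))
  res <- extract_clusters(data, hist, sw$final, sw$registry)
  res$events <- sw$events
  res
}
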