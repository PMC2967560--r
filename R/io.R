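# Delimited-text IO. Event tables travel as CSV/TSV with a header row; this
# is the interchange format the rest of the package speaks. FCS containers
# are not parsed here; export the events to delimited text first.

#' Read an event matrix from a delimited text file
#'
#' @param path CSV/TSV file with a header row (the delimiter is detected by
#'   `data.table::fread`).
#' @param channels Optional channel selection: column names or indices.
#'   Default: all columns.
#' @param format `"delimited"` (default). `"fcs"` is recognized but not
#'   supported: convert FCS containers to delimited text first.
#' @return Numeric event matrix with column names.
#' @export
read_points <- function(path, channels = NULL, format = c("delimited", "fcs")) {
  format <- match.arg(format)
  if (format == "fcs") {
    stop("FCS input is not supported; export the events to CSV/TSV first",
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, header = TRUE)
  if (!is.null(channels)) {
    if (is.numeric(channels)) {
      bad <- channels[channels < 1 | channels > ncol(dt)]
      if (length(bad)) stop("channel index out of range: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      dt <- dt[, as.integer(channels), with = FALSE]
    } else {
      bad <- setdiff(channels, names(dt))
      if (length(bad)) stop("unknown channel(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      dt <- dt[, channels, with = FALSE]
    }
  }
  if (ncol(dt) < 1L) stop("channel selection is empty", call. = FALSE)
  for (j in seq_len(ncol(dt))) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      v <- suppressWarnings(as.numeric(col))
      i <- which(is.na(v) & !is.na(col))[1]
      stop(sprintf("non-numeric value %s at row %d, column '%s'",
                   dQuote(col[i]), i, names(dt)[j]), call. = FALSE)
    }
    if (anyNA(col) || any(!is.finite(col))) {
      i <- which(!is.finite(col))[1]
      stop(sprintf("non-finite value at row %d, column '%s'", i, names(dt)[j]),
           call. = FALSE)
    }
  }
  as.matrix(dt)
}

#' Write an event matrix (optionally with labels) to delimited text
#'
#' Numeric values are written with 17 significant digits, so a write/read
#' round trip through [read_points()] reproduces the events bit-identically.
#'
#' @param data Numeric event matrix; column names are used as the header
#'   (`ch1..chD` when absent).
#' @param path Output CSV path.
#' @param labels Optional integer vector (e.g. ground-truth component
#'   labels), written as a final `label` column.
#' @return `path`, invisibly.
#' @export
write_events <- function(data, path, labels = NULL) {
  data <- as.matrix(data)
  cn <- colnames(data)
  if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(data)))
  dt <- data.table::as.data.table(
    apply(data, 2, function(v) sprintf("%.17g", v)))
  data.table::setnames(dt, cn)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(data))
    dt[["label"]] <- as.integer(labels)
  }
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Write per-event cluster assignments
#'
#' One row per event in the original order: the event's row index and its
#' cluster code (0 = unassigned).
#'
#' @param data The clustered event matrix (row count must match).
#' @param clusters A `cg_clusters` result from the same data.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(data, clusters, path) {
  stopifnot(inherits(clusters, "cg_clusters"))
  n <- nrow(as.matrix(data))
  if (n != clusters$n) stop("clusters were not derived from this data", call. = FALSE)
  assignment <- clusters$assignment
  if (is.null(assignment)) assignment <- integer(n)
  data.table::fwrite(data.table::data.table(index = seq_len(n),
                                            cluster = assignment), path)
  invisible(path)
}

#' Write the cluster summary table
#'
#' Tab-delimited, one row per population sorted by decreasing size: cluster
#' code, peak top level `Lp`, saddle level `Ls`, population size `C`, number
#' of member bins, reliability `f` (three decimals) and the center
#' coordinates.
#'
#' @param clusters A `cg_clusters` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(clusters, path) {
  stopifnot(inherits(clusters, "cg_clusters"))
  df <- summary(clusters)
  if (nrow(df)) df$f <- sprintf("%.3f", df$f)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
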