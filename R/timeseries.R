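#' Node-by-frame time-series matrix
#'
#' Container for BOLD-like multivariate time series: a numeric matrix with one
#' row per node (voxel or region) and one column per acquired frame, the
#' sampling interval `tr` in seconds, and the original frame indices
#' (`frame_ids`) so that provenance survives motion scrubbing.
#'
#' @param values numeric node x frame matrix with no missing values.
#' @param tr sampling interval in seconds per frame (> 0).
#' @param frame_ids strictly increasing integer vector of original frame
#'   indices; defaults to `1:ncol(values)`.
#'
#' @return An object of class `timeseries_matrix`: a list with elements
#'   `values`, `tr` and `frame_ids`.
#' @export
#' @examples
#' ts <- timeseries_matrix(matrix(rnorm(20), 4, 5), tr = 2)
#' n_frames(ts)
timeseries_matrix <- function(values, tr, frame_ids = seq_len(ncol(values))) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("'values' must be a numeric matrix with no missing or non-finite entries")
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("'tr' must be a single positive number (seconds per frame)")
  }
  frame_ids <- as.integer(frame_ids)
  if (length(frame_ids) != ncol(values)) {
    stop("'frame_ids' must have one entry per frame")
  }
  if (ncol(values) > 1L && any(diff(frame_ids) <= 0L)) {
    stop("'frame_ids' must be strictly increasing")
  }
  structure(list(values = values, tr = tr, frame_ids = frame_ids),
            class = "timeseries_matrix")
}

#' @rdname timeseries_matrix
#' @param ts a `timeseries_matrix`.
#' @export
n_frames <- function(ts) ncol(ts$values)

#' @rdname timeseries_matrix
#' @export
n_nodes <- function(ts) nrow(ts$values)

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("timeseries_matrix: %d nodes x %d frames, TR = %g s\n",
              n_nodes(x), n_frames(x), x$tr))
  if (!all(x$frame_ids == seq_len(n_frames(x)))) {
    cat(sprintf("  scrubbed: frame ids span %d..%d with %d gap(s)\n",
                min(x$frame_ids), max(x$frame_ids),
                sum(diff(x$frame_ids) > 1L)))
  }
  invisible(x)
}

#' Read / write time-series matrices as TSV
#'
#' The on-disk format is a plain tab-separated node x frame matrix without row
#' or column names; `tr` and `frame_ids` are supplied by the caller on read.
#'
#' @param ts a `timeseries_matrix`.
#' @param path file path.
#' @inheritParams timeseries_matrix
#' @return `read_timeseries_tsv` returns a `timeseries_matrix`;
#'   `write_timeseries_tsv` returns `path` invisibly.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path, tr, frame_ids = NULL) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  if (is.null(frame_ids)) frame_ids <- seq_len(ncol(values))
  timeseries_matrix(values, tr = tr, frame_ids = frame_ids)
}
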