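#' Pearson correlation matrix of node time series
#'
#' @param ts a [timeseries_matrix()] with at least 3 frames.
#' @return A symmetric node x node numeric matrix of pairwise Pearson
#'   correlations with the diagonal set to 0 (self-correlations are ignored
#'   downstream).
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  if (n_frames(ts) < 3L) stop("at least 3 frames are required")
  v <- apply(ts$values, 1, stats::sd)
  if (any(v == 0)) {
    stop("zero-variance node(s): ", paste(which(v == 0), collapse = ", "))
  }
  r <- stats::cor(t(ts$values))
  diag(r) <- 0
  dimnames(r) <- NULL
  r
}

#' Density-matched target average degree
#'
#' Edge density is matched across subjects through `N = K^S`: for a network of
#' `N` nodes and density exponent `S`, every subject's network is cut to the
#' average degree `K = N^(1/S)`. Exponents between 2 and 3 keep typical
#' functional brain networks connected and reproducible.
#'
#' @param n_nodes number of nodes N (>= 2).
#' @param s density exponent S (> 0).
#' @return The target average degree `K = N^(1/S)`.
#' @export
#' @examples
#' target_degree(10000, 2)    # 100
#' target_degree(10000, 2.5)  # ~39.81
target_degree <- function(n_nodes, s) {
  if (n_nodes < 2L) stop("'n_nodes' must be >= 2")
  if (s <= 0) stop("'s' must be > 0")
  n_nodes^(1 / s)
}

#' Binary undirected network container
#'
#' @param n_nodes number of nodes.
#' @param edges two-column integer matrix of node pairs (1-based); each row is
#'   stored with the smaller index first, duplicates and self-loops rejected.
#' @return An object of class `adjacency_network`: a list with `n_nodes` and
#'   `edges`.
#' @export
adjacency_network <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_nodes)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n_nodes = n_nodes, edges = edges),
            class = "adjacency_network")
}

#' @export
print.adjacency_network <- function(x, ...) {
  k <- if (x$n_nodes > 0) 2 * nrow(x$edges) / x$n_nodes else 0
  cat(sprintf("adjacency_network: %d nodes, %d edges (mean degree %.2f)\n",
              x$n_nodes, nrow(x$edges), k))
  invisible(x)
}

#' Threshold a correlation matrix to a matched edge density
#'
#' Keeps the `E* = round(N * N^(1/S) / 2)` largest positive off-diagonal
#' correlations as binary edges; negative and zero correlations are never
#' edges. Ties at the cut value are broken by `(i, j)` lexicographic order so
#' the edge budget is exact and deterministic. If fewer than `E*` positive
#' correlations exist, all of them become edges and a warning is issued.
#'
#' @param corr symmetric node x node correlation matrix (diagonal ignored).
#' @param s density exponent S of the matching rule `N = K^S`; the default 2.5
#'   sits in the 2-3 range where brain networks stay connected and
#'   reproducible.
#' @return An [adjacency_network()] with attributes `achieved_density`
#'   (fraction of possible edges present) and `edge_budget` (E*).
#' @export
#' @examples
#' ts <- generate_modular_timeseries(
#'   modular_series_spec(30, 3, 0.6, 0.05, n_frames = 300, seed = 1))
#' net <- threshold_to_density(correlation_matrix(ts), s = 2.5)
threshold_to_density <- function(corr, s = 2.5) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n < 2L || ncol(corr) != n) stop("'corr' must be a square matrix with N >= 2")
  if (max(abs(corr - t(corr))) > 1e-12) stop("'corr' must be symmetric")
  budget <- round(n * target_degree(n, s) / 2)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[upper.tri(corr)]
  pos <- vals > 0
  if (sum(pos) < budget) {
    warning(sprintf(paste0("only %d positive correlations available for an ",
                           "edge budget of %d; network is sparser than the ",
                           "matched density"), sum(pos), budget))
  }
  n_take <- min(budget, sum(pos))
  if (n_take > 0) {
    idx <- which(pos)
    ord <- idx[order(-vals[idx], ut[idx, 1], ut[idx, 2])]
    take <- ord[seq_len(n_take)]
    edges <- cbind(ut[take, 1], ut[take, 2])
  } else {
    edges <- matrix(integer(), ncol = 2)
  }
  net <- adjacency_network(n, edges)
  attr(net, "edge_budget") <- budget
  attr(net, "achieved_density") <- nrow(net$edges) / (n * (n - 1) / 2)
  net
}

#' Convert a network to a dense logical adjacency matrix
#'
#' @param net an [adjacency_network()].
#' @return Logical `n_nodes x n_nodes` symmetric matrix.
#' @export
as_adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "adjacency_network"))
  A <- matrix(FALSE, net$n_nodes, net$n_nodes)
  if (nrow(net$edges)) {
    A[net$edges] <- TRUE
    A[net$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

#' Write a network as a 2-column edge list
#'
#' @param net an [adjacency_network()].
#' @param path output file path.
#' @param zero_based write 0-based node indices (the default) or 1-based.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, zero_based = TRUE) {
  e <- net$edges
  if (zero_based) e <- e - 1L
  utils::write.table(e, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes node count of the stored network.
#' @export
read_edge_list <- function(path, n_nodes, zero_based = TRUE) {
  e <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (zero_based) e <- e + 1L
  adjacency_network(n_nodes, e)
}
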