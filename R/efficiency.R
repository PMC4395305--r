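#' @keywords internal
#' @noRd
adjacency_list <- function(net) {
  adj <- vector("list", net$n_nodes)
  if (nrow(net$edges)) {
    ij <- c(net$edges[, 1], net$edges[, 2])
    ji <- c(net$edges[, 2], net$edges[, 1])
    split_adj <- split(ji, factor(ij, levels = seq_len(net$n_nodes)))
    adj <- lapply(split_adj, as.integer)
  } else {
    adj <- rep(list(integer()), net$n_nodes)
  }
  adj
}

bfs_distances <- function(adj, source, n) {
  dist <- rep(Inf, n)
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Hop distances from one node by breadth-first search
#'
#' @param net an [adjacency_network()].
#' @param source source node index (1-based).
#' @return Numeric vector of shortest hop counts from `source` to every node;
#'   0 for the source itself, `Inf` for unreachable nodes.
#' @export
#' @examples
#' path3 <- adjacency_network(3, rbind(c(1, 2), c(2, 3)))
#' shortest_path_lengths(path3, 1)   # 0 1 2
shortest_path_lengths <- function(net, source) {
  stopifnot(inherits(net, "adjacency_network"))
  source <- as.integer(source)
  if (source < 1L || source > net$n_nodes) stop("'source' out of range")
  bfs_distances(adjacency_list(net), source, net$n_nodes)
}

#' Global efficiency of a binary undirected network
#'
#' The mean inverse shortest-path length over all ordered pairs of distinct
#' nodes, `E_global = 1/(N(N-1)) * sum_{j != k} 1/L_{j,k}`, with `1/Inf = 0`
#' for unreachable pairs. Ranges from 0 (edgeless) to 1 (complete graph) and
#' indexes the capacity for integrated, network-wide information transfer.
#'
#' @param net an [adjacency_network()] with at least 2 nodes.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' global_efficiency(adjacency_network(3, rbind(c(1, 2), c(2, 3))))  # 5/6
global_efficiency <- function(net) {
  stopifnot(inherits(net, "adjacency_network"))
  n <- net$n_nodes
  if (n < 2L) stop("global efficiency requires at least 2 nodes")
  adj <- adjacency_list(net)
  total <- 0
  for (src in seq_len(n)) {
    d <- bfs_distances(adj, src, n)[-src]
    total <- total + sum(1 / d)
  }
  total / (n * (n - 1))
}

local_efficiency_of_neighbors <- function(adj, nbrs) {
  k <- length(nbrs)
  if (k < 2L) return(0)
  # induced subgraph on the neighbours, node i itself removed
  sub <- lapply(nbrs, function(v) match(intersect(adj[[v]], nbrs), nbrs))
  total <- 0
  for (s in seq_len(k)) {
    d <- bfs_distances(sub, s, k)[-s]
    total <- total + sum(1 / d)
  }
  total / (k * (k - 1))
}

#' Nodal local efficiency
#'
#' For node `i`, the global efficiency of the subgraph induced by the
#' neighbours of `i` after removing `i` itself: paths must stay inside the
#' neighbourhood. Nodes with fewer than two neighbours score 0 (the
#' normalising pair count is zero).
#'
#' @param net an [adjacency_network()].
#' @param i node index (1-based).
#' @return A number in `[0, 1]`.
#' @export
nodal_local_efficiency <- function(net, i) {
  stopifnot(inherits(net, "adjacency_network"))
  i <- as.integer(i)
  if (i < 1L || i > net$n_nodes) stop("node out of range")
  adj <- adjacency_list(net)
  local_efficiency_of_neighbors(adj, adj[[i]])
}

#' Network local efficiency
#'
#' The unweighted mean of [nodal_local_efficiency()] over all nodes, an index
#' of segregated processing within local neighbourhoods. Degree-0/1 nodes
#' contribute 0 to the average (they have no neighbour pairs).
#'
#' @param net an [adjacency_network()].
#' @return A number in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "adjacency_network"))
  adj <- adjacency_list(net)
  vals <- vapply(seq_len(net$n_nodes), function(i) {
    local_efficiency_of_neighbors(adj, adj[[i]])
  }, numeric(1))
  mean(vals)
}

#' Nodal and network efficiency summary
#'
#' @param net an [adjacency_network()].
#' @return An object of class `efficiency_result`: list with `e_global`,
#'   `e_local`, `nodal_local` (per-node local efficiency), `n_nodes`,
#'   `n_edges`.
#' @export
#' @examples
#' net <- adjacency_network(4, t(combn(4, 2)))  # complete K4
#' efficiency(net)
efficiency <- function(net) {
  stopifnot(inherits(net, "adjacency_network"))
  adj <- adjacency_list(net)
  nodal <- vapply(seq_len(net$n_nodes), function(i) {
    local_efficiency_of_neighbors(adj, adj[[i]])
  }, numeric(1))
  structure(list(e_global = global_efficiency(net),
                 e_local = mean(nodal),
                 nodal_local = nodal,
                 n_nodes = net$n_nodes,
                 n_edges = nrow(net$edges)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency_result: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  E_global = %.4f   E_local = %.4f\n", x$e_global, x$e_local))
  invisible(x)
}
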