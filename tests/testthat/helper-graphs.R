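# Independent graph oracles and small constructors used across tests.
# The Floyd-Warshall oracle shares no code with the package's BFS metrics.

fw_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

fw_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- fw_dist(A)
  sum(1 / D[row(D) != col(D)]) / (n * (n - 1))
}

fw_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    D <- fw_dist(A[nb, nb, drop = FALSE])
    sum(1 / D[row(D) != col(D)]) / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

complete_graph <- function(n) adjacency_network(n, t(combn(n, 2)))

path_graph <- function(n) adjacency_network(n, cbind(1:(n - 1), 2:n))

cycle_graph <- function(n) adjacency_network(n, cbind(1:n, c(2:n, 1)))

star_graph <- function(n) adjacency_network(n, cbind(1L, 2:n))

er_graph <- function(n, p) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  adjacency_network(n, pairs[keep, , drop = FALSE])
}
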