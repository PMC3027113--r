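# Brute-force graph oracles, independent of the package's implementations:
# adjacency counting, triangle enumeration, Floyd-Warshall distances, and
# Floyd-Warshall-based shortest-path counting for betweenness.

random_adjacency <- function(n, p = 0.3) {
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
  adj | t(adj)
}

oracle_degree <- function(adj) rowSums(adj)

oracle_clustering <- function(adj, i) {
  nb <- which(adj[i, ])
  k <- length(nb)
  if (k <= 1) return(0)
  e <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]]) e <- e + 1
    }
  }
  2 * e / (k * (k - 1))
}

floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_closeness <- function(adj, i) {
  d <- floyd_warshall(adj)[i, ]
  reach <- which(is.finite(d) & seq_len(nrow(adj)) != i)
  if (length(reach) == 0) return(0)
  length(reach) / sum(d[reach])
}

# Shortest-path counts by dynamic programming over path length, then the
# pair-fraction sum of betweenness; scaled by n as the package does.
oracle_betweenness_scaled <- function(adj) {
  n <- nrow(adj)
  d <- floyd_warshall(adj)
  # sigma[j,k]: number of shortest j-k paths
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  for (len in seq_len(max(maxd, 1))) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (is.finite(d[j, k]) && d[j, k] == len) {
          # last step comes from a neighbor of k at distance len-1 from j
          pred <- which(adj[, k] & d[j, ] == len - 1)
          sigma[j, k] <- sum(sigma[j, pred])
        }
      }
    }
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (j == i || k == i || !is.finite(d[j, k])) next
        if (is.finite(d[j, i]) && is.finite(d[i, k]) &&
            d[j, i] + d[i, k] == d[j, k]) {
          tot <- tot + sigma[j, i] * sigma[i, k] / sigma[j, k]
        }
      }
    }
    b[i] <- tot
  }
  b / n
}
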