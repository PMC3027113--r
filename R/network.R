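#' Build a protein structure network
#'
#' Vertices are the parsed residues; an undirected edge joins two residues
#' whose side-chain centroids lie within `cutoff` angstroms of each other
#' (inclusive). The default cutoff is 6.5 A.
#'
#' @param model A `structure_model` from [parse_structure()].
#' @param cutoff Contact distance threshold in angstroms.
#' @return A `contact_network` object: logical adjacency matrix, vertex
#'   count `n`, the cutoff, and the parsed residue table.
#' @export
build_network <- function(model, cutoff = 6.5) {
  stopifnot(inherits(model, "structure_model"))
  if (model$n_residues < 2L) stop("need at least 2 residues to build a network")
  coords <- as.matrix(model$residues[, c("x", "y", "z")])
  d <- as.matrix(dist(coords))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  net <- as_contact_network(adj, cutoff = cutoff)
  net$distances <- d
  net$residues <- model$residues
  net
}

#' Construct a contact network from an adjacency matrix
#'
#' Low-level constructor, mainly useful for building small test graphs
#' directly. The matrix is symmetrized and the diagonal cleared.
#'
#' @param adjacency Square logical (or 0/1) matrix.
#' @param cutoff Optional cutoff recorded on the object.
#' @return A `contact_network`.
#' @export
as_contact_network <- function(adjacency, cutoff = NA_real_) {
  adj <- adjacency != 0
  stopifnot(nrow(adj) == ncol(adj))
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  n <- nrow(adj)
  dimnames(adj) <- list(seq_len(n), seq_len(n))
  structure(list(adjacency = adj, n = n, cutoff = cutoff,
                 adjlist = lapply(seq_len(n),
                                  function(i) unname(which(adj[i, ])))),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat("contact_network:", x$n, "vertices,", sum(x$adjacency) / 2,
      "edges, cutoff", x$cutoff, "A\n")
  invisible(x)
}

check_vertex <- function(net, i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > net$n) {
    stop("vertex ", i, " not in network (n = ", net$n, ")")
  }
  i
}

#' Vertex degree
#'
#' Number of residues in direct contact with residue `i`.
#'
#' @param net A `contact_network`.
#' @param i Vertex index (seq_index).
#' @return Non-negative integer.
#' @export
degree <- function(net, i) {
  i <- check_vertex(net, i)
  sum(net$adjacency[i, ])
}

#' Clustering coefficient
#'
#' Fraction of realized contacts among the neighbors of residue `i`:
#' `2 e_i / (k (k - 1))` where `e_i` counts edges between neighbors and `k`
#' is the degree. Vertices with degree <= 1 return 0 (the ratio is 0/0).
#'
#' @inheritParams degree
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, i) {
  i <- check_vertex(net, i)
  nb <- net$adjlist[[i]]
  k <- length(nb)
  if (k <= 1L) return(0)
  e_i <- sum(net$adjacency[nb, nb]) / 2
  2 * e_i / (k * (k - 1))
}

#' Closeness centrality
#'
#' `(N' - 1) / sum_j d(i, j)` over unweighted shortest-path (hop) distances.
#' On a disconnected graph the formula is evaluated within the connected
#' component of `i`, with `N'` the component size; an isolated vertex
#' returns 0.
#'
#' @inheritParams degree
#' @return Value in `(0, 1]` for a non-isolated vertex.
#' @export
closeness <- function(net, i) {
  i <- check_vertex(net, i)
  d <- bfs_distances(net$adjlist, i)
  reach <- which(is.finite(d) & seq_along(d) != i)
  if (length(reach) == 0L) return(0)
  length(reach) / sum(d[reach])
}

#' Length-scaled betweenness centrality
#'
#' Raw betweenness `B(i)` sums, over unordered vertex pairs `{j, k}` not
#' containing `i`, the fraction of shortest `j`-`k` paths that pass through
#' `i`. Because raw betweenness grows with chain length, the returned value
#' is `B(i) / N` with `N` the total vertex count of the network. Pairs in
#' different components contribute nothing.
#'
#' @inheritParams degree
#' @return Non-negative real.
#' @export
betweenness_scaled <- function(net, i) {
  i <- check_vertex(net, i)
  brandes_betweenness(net$adjlist)[i] / net$n
}

#' Contact neighbors of a residue
#'
#' @inheritParams degree
#' @return Integer vector of adjacent vertex indices, ascending.
#' @export
neighbors <- function(net, i) {
  i <- check_vertex(net, i)
  net$adjlist[[i]]
}

#' All four topological features for every residue
#'
#' @param net A `contact_network`.
#' @return Data frame with one row per vertex: `seq_index`, `degree`,
#'   `clustering`, `closeness`, `betweenness` (length-scaled). When the
#'   network came from [build_network()], `aa` is included.
#' @export
network_features <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  n <- net$n
  deg <- rowSums(net$adjacency)
  clus <- vapply(seq_len(n), function(i) clustering_coefficient(net, i),
                 numeric(1))
  clo <- numeric(n)
  for (i in seq_len(n)) {
    d <- bfs_distances(net$adjlist, i)
    reach <- which(is.finite(d) & seq_len(n) != i)
    clo[i] <- if (length(reach) == 0L) 0 else length(reach) / sum(d[reach])
  }
  btw <- brandes_betweenness(net$adjlist) / n
  out <- data.frame(seq_index = seq_len(n), degree = as.integer(deg),
                    clustering = clus, closeness = clo, betweenness = btw)
  if (!is.null(net$residues)) out$aa <- net$residues$aa
  out
}

#' Export the contact network as an edge list
#'
#' @param net A `contact_network` built by [build_network()].
#' @param path Output TSV file (columns i, j, distance).
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(net, path) {
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  d <- if (!is.null(net$distances)) net$distances[idx] else rep(NA_real_, nrow(idx))
  write.table(data.frame(i = idx[, 1], j = idx[, 2], distance = d),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Unweighted single-source shortest-path distances (Inf = unreachable).
bfs_distances <- function(adjlist, src) {
  n <- length(adjlist)
  d <- rep(Inf, n)
  d[src] <- 0
  queue <- integer(n)
  queue[1] <- src
  head_q <- 1L; tail_q <- 1L
  while (head_q <= tail_q) {
    v <- queue[head_q]; head_q <- head_q + 1L
    for (w in adjlist[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        tail_q <- tail_q + 1L
        queue[tail_q] <- w
      }
    }
  }
  d
}

# Brandes' exact betweenness for undirected unweighted graphs; each
# unordered pair counted once.
brandes_betweenness <- function(adjlist) {
  n <- length(adjlist)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    order_visited <- integer(n)
    n_visited <- 0L
    preds <- vector("list", n)
    sigma <- numeric(n); sigma[s] <- 1
    d <- rep(-1L, n); d[s] <- 0L
    queue <- integer(n); queue[1] <- s
    head_q <- 1L; tail_q <- 1L
    while (head_q <= tail_q) {
      v <- queue[head_q]; head_q <- head_q + 1L
      n_visited <- n_visited + 1L
      order_visited[n_visited] <- v
      for (w in adjlist[[v]]) {
        if (d[w] < 0L) {
          d[w] <- d[v] + 1L
          tail_q <- tail_q + 1L
          queue[tail_q] <- w
        }
        if (d[w] == d[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (k in rev(seq_len(n_visited))) {
      w <- order_visited[k]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}
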