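path3 <- function() as_contact_network(rbind(c(0, 1, 0), c(1, 0, 1),
                                             c(0, 1, 0)))
triangle <- function() as_contact_network(matrix(1, 3, 3) - diag(3))
star4 <- function() {
  adj <- matrix(0, 4, 4); adj[1, 2:4] <- 1
  as_contact_network(adj)
}

test_that("the contact rule is inclusive at the cutoff", {
  two_res <- function(d) {
    parse_structure(write_pdb(c(
      pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
      pdb_line(2, "CB", "ALA", "A", 1, 0, 0, 0),
      pdb_line(3, "CA", "ALA", "A", 2, d, 0, 0),
      pdb_line(4, "CB", "ALA", "A", 2, d, 0, 0))))
  }
  expect_equal(sum(build_network(two_res(6.4))$adjacency) / 2, 1)
  expect_equal(sum(build_network(two_res(6.5))$adjacency) / 2, 1)
  expect_equal(sum(build_network(two_res(6.6))$adjacency) / 2, 0)
})

test_that("toy graphs give the hand-computed measures", {
  tri <- triangle()
  expect_equal(degree(tri, 1), 2)
  expect_equal(clustering_coefficient(tri, 1), 1)
  expect_equal(betweenness_scaled(tri, 2), 0)
  expect_equal(closeness(tri, 3), 1)  # complete graph

  p3 <- path3()
  expect_equal(degree(p3, 3), 1)
  expect_equal(closeness(p3, 2), 1)
  expect_equal(closeness(p3, 1), 2 / 3)
  expect_equal(betweenness_scaled(p3, 2), 1 / 3)  # B = 1, N = 3
  expect_equal(clustering_coefficient(p3, 2), 0)

  st <- star4()
  expect_equal(clustering_coefficient(st, 1), 0)
  expect_equal(neighbors(st, 1), 2:4)
  expect_error(degree(st, 9), "not in network")
})

test_that("isolated vertices and disconnected components are handled", {
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 3] <- 1  # P3 component + 2 isolated vertices
  net <- as_contact_network(adj)
  expect_equal(neighbors(net, 4), integer(0))
  expect_equal(closeness(net, 4), 0)
  expect_equal(closeness(net, 2), 1)      # within its component
  expect_equal(closeness(net, 1), 2 / 3)
  expect_equal(betweenness_scaled(net, 2), 1 / 5)  # B = 1, N = 5
})

test_that("all four measures match brute-force oracles on random graphs", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    adj <- random_adjacency(n, runif(1, 0.15, 0.5))
    net <- as_contact_network(adj)
    tf <- network_features(net)
    expect_equal(tf$degree, unname(oracle_degree(adj)))
    expect_equal(tf$clustering,
                 vapply(1:n, function(i) oracle_clustering(adj, i),
                        numeric(1)),
                 tolerance = 1e-12)
    expect_equal(tf$closeness,
                 vapply(1:n, function(i) oracle_closeness(adj, i),
                        numeric(1)),
                 tolerance = 1e-12)
    expect_equal(tf$betweenness, oracle_betweenness_scaled(adj),
                 tolerance = 1e-12)
  }
})

test_that("measures agree with igraph on connected random graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    adj <- random_adjacency(n, 0.4)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (!igraph::is_connected(g)) next
    net <- as_contact_network(adj)
    tf <- network_features(net)
    expect_equal(tf$degree, unname(igraph::degree(g)))
    expect_equal(tf$closeness,
                 unname((n - 1) * igraph::closeness(g)),
                 tolerance = 1e-10)
    expect_equal(tf$betweenness, unname(igraph::betweenness(g)) / n,
                 tolerance = 1e-10)
    expect_equal(tf$clustering,
                 ifelse(is.nan(igraph::transitivity(g, type = "local")), 0,
                        igraph::transitivity(g, type = "local")),
                 tolerance = 1e-10)
  }
})

test_that("handshake lemma and relabeling invariance hold", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    adj <- random_adjacency(n, 0.3)
    net <- as_contact_network(adj)
    expect_equal(sum(network_features(net)$degree), sum(adj))
    perm <- sample(n)
    tf1 <- network_features(net)
    tf2 <- network_features(as_contact_network(adj[perm, perm]))
    # vertex i of the permuted graph is vertex perm[i] of the original
    expect_equal(tf2$degree, tf1$degree[perm])
    expect_equal(tf2$closeness, tf1$closeness[perm], tolerance = 1e-12)
    expect_equal(tf2$betweenness, tf1$betweenness[perm], tolerance = 1e-12)
    expect_equal(tf2$clustering, tf1$clustering[perm], tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases the closeness of its endpoints", {
  set.seed(29)
  for (rep in 1:10) {
    n <- 12
    adj <- random_adjacency(n, 0.25)
    free <- which(!adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(free) == 0) next
    pick <- free[sample(nrow(free), 1), ]
    before <- c(closeness(as_contact_network(adj), pick[1]),
                closeness(as_contact_network(adj), pick[2]))
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- TRUE
    after <- c(closeness(as_contact_network(adj2), pick[1]),
               closeness(as_contact_network(adj2), pick[2]))
    expect_true(all(after >= before - 1e-12))
  }
})

test_that("network round-trips from a real structure and exports TSVs", {
  m <- parse_structure(toy3_pdb())
  net <- build_network(m, cutoff = 6.5)
  # distances: r1-r2 = sqrt(26) < 6.5, r1-r3 = sqrt(26), r2-r3 = sqrt(50)
  expect_equal(sum(net$adjacency) / 2, 2)
  tsv <- tempfile()
  write_edge_tsv(net, tsv)
  edges <- read.delim(tsv)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$distance, rep(sqrt(26), 2), tolerance = 1e-6)
})
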