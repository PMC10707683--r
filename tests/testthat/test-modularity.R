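# seeded random labels helper local to this file
with_seed_labels <- function(seed, n) {
  set.seed(seed * 131)
  sample.int(4, n, replace = TRUE)
}

test_that("ng_null matches closed forms and conserves total weight", {
  tri <- induced_subnetwork(make_two_triangles(), as.character(1:3))
  P <- ng_null(tri)
  expect_equal(unname(P), matrix(2 / 3, 3, 3))

  edge <- weighted_network(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(ng_null(edge)), matrix(0.5, 2, 2))

  for (s in 1:5) {
    net <- random_weighted_network(20, 0.25, seed = s)
    expect_equal(sum(ng_null(net)), total_weight(net))
  }

  empty <- weighted_network(matrix(0, 3, 3))
  expect_error(ng_null(empty), "2U = 0")
})

test_that("modularity matches the brute-force double-sum oracle", {
  # two disjoint triangles, planted partition: frozen closed value 6
  net <- make_two_triangles(bridge = FALSE)
  p <- partition(c(1, 1, 1, 2, 2, 2), as.character(1:6))
  expect_equal(modularity_q(net, p), 6)
  expect_equal(modularity_q(net, p),
               oracle_modularity(net$weights, as.integer(p)))

  # random networks and partitions against the oracle
  for (s in 1:10) {
    net <- random_weighted_network(9, 0.4, seed = s)
    lab <- with_seed_labels(s, 9)
    p <- partition(lab, net$node_ids)
    for (g in c(0.5, 1, 1.7))
      expect_equal(modularity_q(net, p, gamma = g),
                   oracle_modularity(net$weights, lab, gamma = g),
                   tolerance = 1e-12)
  }
})

test_that("one-community Q is 0 and singleton Q is the closed form", {
  for (s in 1:8) {
    net <- random_weighted_network(12, 0.3, seed = s)
    n <- n_nodes(net)
    expect_equal(modularity_q(net, partition(rep(1, n), net$node_ids)), 0,
                 tolerance = 1e-10)
    k <- strengths(net)
    expect_equal(modularity_q(net, partition(seq_len(n), net$node_ids)),
                 -sum(k^2) / total_weight(net), tolerance = 1e-10)
  }
})

test_that("modularity agrees with igraph's on the normalized scale", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    net <- random_weighted_network(15, 0.3, seed = s)
    g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                             weighted = TRUE)
    lab <- with_seed_labels(s + 50, 15)
    p <- partition(lab, net$node_ids)
    expect_equal(modularity_q(net, p, normalized = TRUE),
                 igraph::modularity(g, lab,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("louvain recovers the two-triangle fixture and attains the
           exhaustive-enumeration maximum", {
  net <- make_two_triangles(bridge = TRUE)
  p <- louvain_optimize(net, seed = 7)
  expect_equal(as.integer(p), c(1, 1, 1, 2, 2, 2))

  parts <- enumerate_partitions(6)
  best <- max(vapply(parts, function(lab)
    oracle_modularity(net$weights, lab), numeric(1)))
  expect_equal(modularity_q(net, p), best, tolerance = 1e-10)
})

test_that("louvain degenerate and contract cases", {
  empty <- weighted_network(matrix(0, 4, 4))
  expect_equal(as.integer(louvain_optimize(empty)), 1:4)

  # isolated node stays a singleton
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[1, 3] <- A[3, 1] <- 1
  net <- weighted_network(A)
  p <- louvain_optimize(net, seed = 1)
  expect_equal(sum(as.integer(p) == as.integer(p)[4]), 1)

  # determinism and at-least-singleton quality
  for (s in 1:5) {
    net <- random_weighted_network(14, 0.3, seed = s)
    p1 <- louvain_optimize(net, seed = 11)
    p2 <- louvain_optimize(net, seed = 11)
    expect_identical(as.integer(p1), as.integer(p2))
    qs <- modularity_q(net, partition(seq_len(14), net$node_ids))
    expect_gte(modularity_q(net, p1), qs)
  }
})

test_that("exhaustive enumeration bounds the optimizer for small n", {
  for (s in 1:4) {
    net <- random_weighted_network(7, 0.45, seed = s + 20)
    best <- max(vapply(enumerate_partitions(7), function(lab)
      oracle_modularity(net$weights, lab), numeric(1)))
    q <- modularity_q(net, louvain_optimize(net, seed = s))
    expect_lte(q, best + 1e-9)
  }
})
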