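test_that("association_matrix covers the three canonical cases", {
  p <- partition(c(a = 1, b = 1, c = 2))
  expect_equal(unname(association_matrix(p)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(unname(association_matrix(partition(c(a = 1, b = 1, c = 1)))),
               matrix(1, 3, 3))
  expect_equal(unname(association_matrix(partition(c(a = 1, b = 2, c = 3)))),
               diag(3))
})

test_that("mean_weight_matrix averages correctly and stays in [0,1]", {
  e <- partition_ensemble(list(partition(c(a = 1, b = 1, c = 2)),
                               partition(c(a = 1, b = 2, c = 2))))
  W <- mean_weight_matrix(e)
  expect_equal(W["a", "b"], 0.5)
  expect_equal(W["b", "c"], 0.5)
  expect_equal(W["a", "c"], 0)
  expect_equal(diag(W), c(a = 1, b = 1, c = 1))

  # idempotence on identical members
  e2 <- partition_ensemble(rep(list(partition(c(a = 1, b = 1, c = 2))), 5))
  expect_equal(mean_weight_matrix(e2),
               association_matrix(partition(c(a = 1, b = 1, c = 2))))

  # random ensembles: symmetry and range
  set.seed(42)
  for (rep in 1:5) {
    parts <- lapply(1:6, function(i)
      partition(sample.int(3, 8, replace = TRUE), letters[1:8]))
    W <- mean_weight_matrix(partition_ensemble(parts))
    expect_identical(W, t(W))
    expect_true(all(W >= 0 & W <= 1))
  }
  expect_error(mean_weight_matrix(e, integer(0)), "empty selection")
})

test_that("filtered_adjacency is the Hadamard product and never inflates", {
  tri <- induced_subnetwork(make_two_triangles(), as.character(1:3))
  ones <- matrix(1, 3, 3)
  expect_identical(filtered_adjacency(tri, ones)$weights, tri$weights)
  expect_equal(total_weight(filtered_adjacency(tri, diag(3))), 0)

  W <- ones; W[1, 2] <- W[2, 1] <- 0.5
  half <- filtered_adjacency(tri, W)
  expect_equal(unname(strengths(half)), c(1.5, 1.5, 2))

  set.seed(7)
  net <- random_weighted_network(10, 0.4, seed = 3)
  Wr <- matrix(runif(100), 10, 10)
  Wr <- (Wr + t(Wr)) / 2
  diag(Wr) <- 1
  expect_true(all(filtered_adjacency(net, Wr)$weights <= net$weights + 1e-15))
  expect_error(filtered_adjacency(net, matrix(1, 3, 3)), "shape")
})

test_that("build_partition_pool is seed-derived and detects stability", {
  net <- make_two_triangles(bridge = TRUE)
  # L = 1 equals a single run with the derived child seed
  pool1 <- build_partition_pool(net, 1, seed = 9)
  direct <- louvain_optimize(net, seed = spawn_seeds(9, 1)[1])
  expect_identical(as.integer(pool1$partitions[[1]]), as.integer(direct))

  # strong structure: all pool members identical, block co-assignment
  pool <- build_partition_pool(net, 10, seed = 2)
  labs <- unique(apply(ensemble_label_matrix(pool), 2, paste, collapse = ","))
  expect_length(labs, 1)
  W <- mean_weight_matrix(pool)
  blocks <- association_matrix(partition(c(1, 1, 1, 2, 2, 2),
                                         as.character(1:6)))
  expect_equal(W, blocks)
})

test_that("wmm reduces to MM on stable structure and is deterministic", {
  net <- make_two_triangles(bridge = TRUE)
  res <- wmm(net, pool_size = 10, n_selected = 5, n_selections = 5,
             seed = 3, details = TRUE)
  expect_identical(as.integer(res$partition),
                   as.integer(louvain_optimize(net, seed = 1)))
  blocks <- association_matrix(partition(c(1, 1, 1, 2, 2, 2),
                                         as.character(1:6)))
  expect_equal(res$weight_matrix, blocks)

  # L = M = K = 1 boundary runs and returns a valid partition
  p1 <- wmm(net, 1, 1, 1, seed = 5)
  expect_s3_class(p1, "partition")
  expect_length(p1, 6)

  p_a <- wmm(net, 8, 4, 4, seed = 12)
  p_b <- wmm(net, 8, 4, 4, seed = 12)
  expect_identical(as.integer(p_a), as.integer(p_b))
})

test_that("pool instability exists on noisy benchmarks and wmm stabilizes", {
  g <- generate_weighted_benchmark(benchmark_spec(50, 3, 9, 0.6, seed = 4))
  pool <- build_partition_pool(g$network, 30, seed = 6)
  labs <- unique(apply(ensemble_label_matrix(pool), 2, paste, collapse = ","))
  expect_gt(length(labs), 1)
})

test_that("robust_mm is more stable than plain MM on a noisy benchmark", {
  # direction of the published stability comparison, at reduced replication
  g <- generate_weighted_benchmark(benchmark_spec(300, 15, 75, 0.6,
                                                  seed = 77))
  rs <- spawn_seeds(78, 20)
  pm <- lapply(1:10, function(r) louvain_optimize(g$network, seed = rs[r]))
  pr <- lapply(1:10, function(r) robust_mm(g$network, seed = rs[10 + r]))
  expect_lte(mean_average_node_entropy(partition_ensemble(pr)),
             mean_average_node_entropy(partition_ensemble(pm)))
})

test_that("robust_mm recovers planted structure and documents its tie rule", {
  net <- make_two_triangles(bridge = TRUE)
  p <- robust_mm(net, pool_size = 20, seed = 8)
  expect_equal(nmi(p, partition(c(1, 1, 1, 2, 2, 2), as.character(1:6))), 1)

  # identical one-community pool: strict threshold empties the matrix,
  # yielding all singletons
  edge <- weighted_network(matrix(c(0, 1, 1, 0), 2, 2))
  p2 <- robust_mm(edge, pool_size = 5, n_null = 100, seed = 1)
  expect_equal(n_communities(p2), 2)
})
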