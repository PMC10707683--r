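test_that("generated networks satisfy the structural contract", {
  for (s in 1:5) {
    g <- generate_weighted_benchmark(benchmark_spec(80, 6, 20, 0.3,
                                                    seed = s))
    A <- g$network$weights
    expect_identical(A, t(A))
    expect_true(all(A >= 0))
    expect_equal(unname(diag(A)), rep(0, 80))
    expect_length(g$partition, 80)
    expect_equal(sum(community_sizes(g$partition)), 80)
  }
})

test_that("zero mixing gives disconnected communities recoverable by
           components", {
  g <- generate_weighted_benchmark(benchmark_spec(60, 8, 20, 0, seed = 3))
  comm <- as.integer(g$partition)
  cross <- g$network$weights[outer(comm, comm, "!=")]
  expect_equal(sum(cross), 0)
  comp <- oracle_components(g$network$weights)
  expect_equal(nmi(partition(comp, g$network$node_ids), g$partition), 1)
})

test_that("realized moments track the spec (20 networks, N=100, mu=0.2)", {
  md <- mx <- numeric(20)
  for (i in 1:20) {
    g <- generate_weighted_benchmark(benchmark_spec(100, 5, 25, 0.2,
                                                    tau1 = 2, tau2 = 1,
                                                    beta = 1.5, seed = i))
    A <- g$network$weights > 0
    md[i] <- mean(rowSums(A))
    comm <- as.integer(g$partition)
    mx[i] <- sum(A & outer(comm, comm, "!=")) / sum(A)
  }
  expect_lt(abs(mean(md) - 5) / 5, 0.10)
  expect_lt(abs(mean(mx) - 0.2), 0.05)
})

test_that("strength mixing tracks mu_w and generation is seed-deterministic", {
  g1 <- generate_weighted_benchmark(benchmark_spec(300, 15, 75, 0.4,
                                                   seed = 17))
  g2 <- generate_weighted_benchmark(benchmark_spec(300, 15, 75, 0.4,
                                                   seed = 17))
  expect_identical(g1$network$weights, g2$network$weights)
  expect_identical(as.integer(g1$partition), as.integer(g2$partition))

  W <- g1$network$weights
  comm <- as.integer(g1$partition)
  smix <- sum(W[outer(comm, comm, "!=")]) / sum(W)
  expect_lt(abs(smix - 0.4), 0.05)
})

test_that("attributed benchmarks are unweighted with center-separated
           attributes", {
  spec <- attributed_benchmark_spec(120, 8, 30, 0.3, tau1 = 2, tau2 = 1.5,
                                    seed = 5, attribute_sd = 0.05)
  g <- generate_attributed_benchmark(spec)
  expect_true(all(g$network$weights %in% c(0, 1)))
  expect_equal(dim(g$attributes$values), c(120, 3))
  expect_identical(g$attributes$node_ids, g$network$node_ids)

  # sigma -> 0: within-community spread << between-community separation
  D <- distance_matrix(g$attributes)
  comm <- as.integer(g$partition)
  same <- outer(comm, comm, "==") & upper.tri(D)
  diff <- outer(comm, comm, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), 0.3)
  expect_gt(mean(D[diff]), 0.8)
})

test_that("hierarchical fixture nests its two truth levels", {
  fx <- generate_hierarchical_fixture(2, 2, 15, 0.8, 0.3, 0.02,
                                      spatial_sep = 4, sigma = 0.3, seed = 2)
  l1 <- as.integer(fx$level1)
  l2 <- as.integer(fx$level2)
  tab <- table(l2, l1)
  expect_true(all(rowSums(tab > 0) == 1))

  # degenerate probabilities: everything disconnects into sub-blocks
  fx0 <- generate_hierarchical_fixture(2, 2, 10, 0.9, 1e-9, 0, seed = 1)
  comp <- oracle_components(fx0$network$weights)
  expect_gte(length(unique(comp)), 4)

  expect_error(generate_hierarchical_fixture(p_in_sub = 0.2,
                                             p_in_super = 0.5, p_out = 0.01))
})

test_that("experiment_grid honors the published row structure", {
  g1 <- experiment_grid(1)
  n100 <- Filter(function(s) s$n_nodes == 100, g1)
  expect_length(n100, 7)
  expect_equal(vapply(n100, `[[`, numeric(1), "mu_t"),
               seq(0.2, 0.8, by = 0.1))
  n50 <- Filter(function(s) s$n_nodes == 50, g1)
  expect_length(n50, 6)
  expect_equal(max(vapply(n50, `[[`, numeric(1), "mu_t")), 0.7)
  # replication multiplies counts and keeps deterministic ordering
  g2 <- experiment_grid(2, seed = 1)
  expect_length(g2, 2 * length(g1))
  expect_identical(vapply(g2[1:2], `[[`, numeric(1), "mu_t"), c(0.2, 0.2))
})
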