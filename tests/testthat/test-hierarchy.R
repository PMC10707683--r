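test_that("distance_matrix computes Euclidean distances", {
  at <- node_attributes(rbind(c(0, 0, 0), c(3, 4, 0)), c("a", "b"))
  D <- distance_matrix(at)
  expect_equal(D["a", "b"], 5)
  expect_equal(diag(D), c(a = 0, b = 0))

  same <- node_attributes(matrix(1, 3, 2), letters[1:3])
  expect_equal(unname(distance_matrix(same)), matrix(0, 3, 3))

  one <- node_attributes(matrix(c(0, 1, 3), 3, 1), letters[1:3])
  expect_equal(unname(distance_matrix(one)),
               rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)))
})

test_that("community_distance implements the 1/N^2 mean with zero diagonal", {
  one <- node_attributes(matrix(c(0, 1, 3), 3, 1), letters[1:3])
  D <- distance_matrix(one)
  expect_equal(community_distance("a", D), 0)
  at2 <- node_attributes(rbind(c(0, 0, 0), c(3, 4, 0)), c("a", "b"))
  expect_equal(community_distance(c("a", "b"), distance_matrix(at2)), 2.5)
  expect_equal(community_distance(letters[1:3], D), 12 / 9)
})

test_that("post_subdivision_distance is the unweighted sub-community mean", {
  one <- node_attributes(matrix(c(0, 1, 3), 3, 1), letters[1:3])
  D <- distance_matrix(one)
  # no split: equals the community distance
  expect_equal(post_subdivision_distance(partition(c(a = 1, b = 1, c = 1)), D),
               community_distance(letters[1:3], D))
  # split {a,b} | {c}: mean(0.5, 0) = 0.25
  expect_equal(post_subdivision_distance(partition(c(a = 1, b = 1, c = 2)), D),
               0.25)
  # all singletons: 0
  expect_equal(post_subdivision_distance(partition(c(a = 1, b = 2, c = 3)), D),
               0)
})

test_that("permutation_test accepts true spatial splits and rejects noise", {
  set.seed(3)
  # two tight clusters far apart
  pts <- rbind(matrix(rnorm(20 * 3, 0, 0.1), 20),
               matrix(rnorm(20 * 3, 10, 0.1), 20))
  at <- node_attributes(pts, as.character(1:40))
  D <- distance_matrix(at)
  split <- partition(rep(1:2, each = 20), as.character(1:40))
  res <- permutation_test(split, D, n_perm = 2000, seed = 1)
  expect_true(res$accepted)
  expect_lt(res$d_after, res$null_quantile)

  # a split indistinguishable from a shuffle
  rnd <- partition(sample(rep(1:2, each = 20)), as.character(1:40))
  res2 <- permutation_test(rnd, D, n_perm = 2000, seed = 2)
  expect_false(res2$accepted)

  expect_error(permutation_test(partition(rep(1, 40), as.character(1:40)), D),
               "at least 2")
  expect_error(permutation_test(split, D, n_perm = 10, alpha = 0.05),
               "quantile undefined")
})

test_that("two_step_wmm recovers a planted hierarchy and refines level 1", {
  fx <- generate_hierarchical_fixture(2, 2, 25, 0.8, 0.3, 0.02,
                                      spatial_sep = 5, sigma = 0.5, seed = 4)
  h <- two_step_wmm(fx$network, fx$attributes, n_perm = 2000,
                    pool_size = 30, n_selected = 15, n_selections = 15,
                    seed = 1)
  expect_equal(nmi(h$level1, fx$level1), 1)
  expect_equal(nmi(h$level2, fx$level2), 1)

  # refinement: every level-2 community is inside one level-1 community
  tab <- table(as.integer(h$level2), as.integer(h$level1)[
    match(names(h$level2), names(h$level1))])
  expect_true(all(rowSums(tab > 0) == 1))
  # provenance maps level-2 labels to their parents
  expect_true(all(names(table(as.integer(h$level2))) %in%
                    names(h$provenance)))

  # determinism
  h2 <- two_step_wmm(fx$network, fx$attributes, n_perm = 2000,
                     pool_size = 30, n_selected = 15, n_selections = 15,
                     seed = 1)
  expect_identical(as.integer(h$level2), as.integer(h2$level2))
})

test_that("communities below min_subdivide_size pass through untouched", {
  fx <- generate_hierarchical_fixture(2, 2, 10, 0.8, 0.3, 0.02,
                                      spatial_sep = 5, sigma = 0.5, seed = 6)
  h <- two_step_wmm(fx$network, fx$attributes, n_perm = 500,
                    min_subdivide_size = 1000,
                    pool_size = 10, n_selected = 5, n_selections = 5,
                    seed = 2)
  expect_identical(as.integer(h$level2), as.integer(h$level1))
  expect_true(all(!vapply(h$test_results, `[[`, logical(1), "tested")))
})

test_that("two_step_wmm contracts: attribute mismatch and empty network", {
  fx <- generate_hierarchical_fixture(2, 2, 10, 0.8, 0.3, 0.02, seed = 1)
  bad <- node_attributes(fx$attributes$values[1:10, ],
                         fx$attributes$node_ids[1:10])
  expect_error(two_step_wmm(fx$network, bad), "cover")
})
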