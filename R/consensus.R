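#' Binary association (co-assignment) matrix of a partition
#'
#' `T_ij = 1` iff nodes `i` and `j` share a community label; diagonal 1.
#'
#' @param partition a [partition()].
#' @return symmetric 0/1 matrix with node-id dimnames.
#' @export
association_matrix <- function(partition) {
  if (!is_partition(partition)) partition <- partition(partition)
  lab <- as.integer(partition)
  M <- outer(lab, lab, "==") * 1.0
  dimnames(M) <- list(names(partition), names(partition))
  M
}

#' Build a partition pool by repeated modularity maximization
#'
#' Runs [louvain_optimize()] `pool_size` times with independently derived
#' child seeds (see [spawn_seeds()]); the run-to-run variability of the
#' optimizer is what the downstream consensus stages exploit.
#'
#' @param network a [weighted_network()].
#' @param pool_size number of runs `L` (paper-default 100).
#' @param gamma resolution parameter.
#' @param seed root seed.
#' @return a [partition_ensemble()] of size `pool_size`.
#' @export
build_partition_pool <- function(network, pool_size = 100L, gamma = 1,
                                 seed = 1L) {
  stopifnot(pool_size >= 1)
  seeds <- spawn_seeds(seed, pool_size)
  partition_ensemble(lapply(seeds, function(s)
    louvain_optimize(network, gamma = gamma, seed = s)))
}

#' Mean co-assignment weight matrix of an ensemble subset
#'
#' Elementwise mean of the binary association matrices of the selected
#' ensemble members: `W_ij` estimates the probability that `i` and `j`
#' land in the same community. Entries lie in `[0, 1]`, diagonal 1.
#'
#' @param ensemble a [partition_ensemble()].
#' @param indices subset of member indices (default: all).
#' @return symmetric numeric matrix in `[0, 1]`.
#' @export
mean_weight_matrix <- function(ensemble, indices = NULL) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  if (is.null(indices)) indices <- seq_len(ensemble$size)
  if (!length(indices)) stop("empty selection")
  stopifnot(all(indices >= 1), all(indices <= ensemble$size))
  nodes <- names(ensemble$partitions[[1]])
  n <- length(nodes)
  acc <- matrix(0, n, n)
  for (i in indices) {
    lab <- as.integer(ensemble$partitions[[i]])
    acc <- acc + (outer(lab, lab, "==") * 1.0)
  }
  W <- acc / length(indices)
  dimnames(W) <- list(nodes, nodes)
  W
}

#' Filter an adjacency matrix by a weight matrix (Hadamard product)
#'
#' `A'_ij = W_ij * A_ij`: edges with low co-assignment probability are
#' attenuated, sharpening community structure. With `W <= 1` elementwise
#' no edge weight ever increases. The downstream null model is recomputed
#' from the filtered strengths.
#'
#' @param network a [weighted_network()].
#' @param W weight matrix (`N x N`, entries in `[0, 1]`).
#' @return a [weighted_network()] over the same nodes.
#' @export
filtered_adjacency <- function(network, W) {
  stopifnot(is_weighted_network(network))
  W <- as.matrix(W)
  if (!all(dim(W) == dim(network$weights)))
    stop("weight matrix shape mismatch")
  weighted_network(network$weights * W, network$node_ids)
}

# Stack of association matrices as an N^2 x L matrix (BLAS-friendly),
# falling back to nothing special: used only when memory allows.
assoc_stack <- function(label_matrix) {
  cpp_assoc_flat(label_matrix)
}

#' Weighted modularity maximization (WMM)
#'
#' Consensus-filtered community detection in five stages, all driven by
#' one root seed:
#' \enumerate{
#'   \item a pool of `pool_size` (L) Louvain partitions of `A`;
#'   \item `n_selections` (K) random subsets of `n_selected` (M) pool
#'     members, drawn without replacement, each averaged into a first-round
#'     weight matrix `W_i`;
#'   \item a Louvain run on each filtered matrix `A * W_i`;
#'   \item the final weight matrix `W'` = mean association matrix of those
#'     K second-round partitions;
#'   \item a final Louvain run on `A * W'`.
#' }
#'
#' @param network a [weighted_network()].
#' @param pool_size pool size L (default 100).
#' @param n_selected partitions per selection M (default 50).
#' @param n_selections number of selections K (default 50).
#' @param gamma resolution parameter (default 1).
#' @param seed root seed; the run is exactly reproducible.
#' @param details if `TRUE`, also return the final weight matrix and the
#'   pool.
#' @return a [partition()]; with `details = TRUE` a list with elements
#'   `partition`, `weight_matrix`, `pool`.
#' @export
wmm <- function(network, pool_size = 100L, n_selected = 50L,
                n_selections = 50L, gamma = 1, seed = 1L, details = FALSE) {
  stopifnot(is_weighted_network(network))
  L <- as.integer(pool_size); M <- as.integer(n_selected)
  K <- as.integer(n_selections)
  stopifnot(M >= 1, M <= L, K >= 1)
  if (total_weight(network) <= 0) stop("empty network: 2U = 0")
  n <- n_nodes(network)
  A <- network$weights

  s <- spawn_seeds(seed, 4)
  pool_seeds <- spawn_seeds(s[1], L)
  second_seeds <- spawn_seeds(s[2], K)
  selections <- with_seed(s[3], lapply(seq_len(K), function(i)
    sample.int(L, M, replace = FALSE)))

  pool_labels <- matrix(0L, n, L)
  for (l in seq_len(L))
    pool_labels[, l] <- as.integer(cpp_louvain(A, gamma, pool_seeds[l], 50L,
                                               1e-12))

  acc <- matrix(0, n, n)
  if (as.double(n) * n * L <= 4e7) {
    # one BLAS product computes all K first-round weight matrices
    flat <- assoc_stack(pool_labels)
    Sel <- matrix(0, L, K)
    for (i in seq_len(K)) Sel[selections[[i]], i] <- 1 / M
    Wflat <- flat %*% Sel
    for (i in seq_len(K)) {
      Wi <- matrix(Wflat[, i], n, n)
      labi <- cpp_louvain(A * Wi, gamma, second_seeds[i], 50L, 1e-12)
      acc <- acc + (outer(labi, labi, "==") * 1.0)
    }
  } else {
    for (i in seq_len(K)) {
      Wi <- matrix(0, n, n)
      for (l in selections[[i]]) {
        lab <- pool_labels[, l]
        Wi <- Wi + (outer(lab, lab, "==") * 1.0)
      }
      Wi <- Wi / M
      labi <- cpp_louvain(A * Wi, gamma, second_seeds[i], 50L, 1e-12)
      acc <- acc + (outer(labi, labi, "==") * 1.0)
    }
  }
  Wfinal <- acc / K
  final <- cpp_louvain(A * Wfinal, gamma, s[4], 50L, 1e-12)
  p <- partition(final, network$node_ids)
  if (!details) return(p)
  dimnames(Wfinal) <- list(network$node_ids, network$node_ids)
  pool <- partition_ensemble(lapply(seq_len(L), function(l)
    partition(pool_labels[, l], network$node_ids)))
  list(partition = p, weight_matrix = Wfinal, pool = pool)
}

#' Robust modularity maximization (consensus-thresholding baseline)
#'
#' Bassett-style stabilization: the mean association matrix of a pool of
#' `pool_size` Louvain runs is thresholded against a permutation null in
#' which each pool partition's community labels are randomly reassigned to
#' nodes (community sizes preserved); entries not strictly exceeding the
#' `(1 - alpha)` quantile of the null association values are zeroed, and a
#' final Louvain run is applied to the thresholded matrix.
#'
#' The null entry for a node pair under independent label permutations is
#' distributed as the mean of independent Bernoulli(`p_m`) draws with
#' `p_m = sum_c n_c (n_c - 1) / (N (N - 1))` for pool member `m`; the
#' implementation samples this exact marginal law `n_null` times rather
#' than materializing permuted matrices.
#'
#' @param network a [weighted_network()].
#' @param pool_size pool size L (default 100).
#' @param n_null null draws (default 1000).
#' @param alpha significance level for the threshold (default 0.05).
#' @param gamma resolution parameter.
#' @param seed root seed.
#' @param details if `TRUE`, return threshold and matrices too.
#' @return a [partition()] (or a list when `details = TRUE`).
#' @export
robust_mm <- function(network, pool_size = 100L, n_null = 1000L,
                      alpha = 0.05, gamma = 1, seed = 1L, details = FALSE) {
  stopifnot(is_weighted_network(network), pool_size >= 2, n_null >= 1,
            alpha > 0, alpha < 1)
  if (total_weight(network) <= 0) stop("empty network: 2U = 0")
  n <- n_nodes(network)
  s <- spawn_seeds(seed, 3)
  pool <- build_partition_pool(network, pool_size, gamma = gamma, seed = s[1])
  sizes_list <- lapply(pool$partitions, community_sizes)
  p_m <- vapply(sizes_list, function(sz)
    sum(as.numeric(sz) * (as.numeric(sz) - 1)) / (n * (n - 1)), numeric(1))
  if (all(p_m == 0))
    stop("degenerate pool: every partition is all-singleton")
  Wbar <- mean_weight_matrix(pool)
  nullvals <- with_seed(s[2], {
    draws <- matrix(rbinom(n_null * pool_size, 1L,
                           rep(p_m, each = n_null)),
                    nrow = n_null, ncol = pool_size)
    rowMeans(draws)
  })
  thr <- sort(nullvals)[ceiling(n_null * (1 - alpha))]
  Wthr <- Wbar
  Wthr[Wbar <= thr] <- 0
  diag(Wthr) <- 0
  lab <- cpp_louvain(Wthr, gamma, s[3], 50L, 1e-12)
  p <- partition(lab, network$node_ids)
  if (!details) return(p)
  list(partition = p, association = Wbar, threshold = thr, pool = pool)
}
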