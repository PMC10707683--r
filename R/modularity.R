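#' Newman-Girvan null model matrix
#'
#' Expected edge weight under random wiring preserving node strengths:
#' \eqn{P_{ij} = k_i k_j / 2U}. Conserves total weight:
#' \eqn{\sum_{ij} P_{ij} = 2U}.
#'
#' @param network a [weighted_network()].
#' @return `N x N` numeric matrix.
#' @export
ng_null <- function(network) {
  stopifnot(is_weighted_network(network))
  twoU <- total_weight(network)
  if (twoU <= 0) stop("empty network: 2U = 0")
  k <- strengths(network)
  outer(k, k) / twoU
}

#' Modularity of a partition
#'
#' Unnormalized modularity with resolution parameter `gamma`:
#' \deqn{Q = \sum_{ij} [A_{ij} - \gamma k_i k_j / 2U]\,\delta(\sigma_i, \sigma_j)}
#' summed over all ordered pairs including `i = j` (where `A_ii = 0` and
#' the null term is `k_i^2/2U`). The conventional `1/2U` prefactor is
#' omitted; partitions ranked by Q are unaffected. Set
#' `normalized = TRUE` to divide by `2U` for display.
#'
#' @param network a [weighted_network()].
#' @param partition a [partition()] covering the network's nodes.
#' @param gamma resolution parameter (> 0), default 1.
#' @param normalized divide by `2U`? Default `FALSE`.
#' @return scalar Q.
#' @export
modularity_q <- function(network, partition, gamma = 1, normalized = FALSE) {
  stopifnot(is_weighted_network(network), gamma > 0)
  if (!is_partition(partition)) partition <- partition(partition)
  if (!setequal(names(partition), network$node_ids))
    stop("partition and network cover different node sets")
  lab <- as.integer(partition)[match(network$node_ids, names(partition))]
  A <- network$weights
  twoU <- sum(A)
  if (twoU <= 0) stop("empty network: 2U = 0")
  k <- rowSums(A)
  same <- outer(lab, lab, "==")
  Q <- sum(A[same]) - gamma * sum(outer(k, k)[same]) / twoU
  if (normalized) Q / twoU else Q
}

#' Louvain-style greedy modularity optimizer
#'
#' Locally greedy two-phase optimizer of [modularity_q()]: seeded random
#' node orders per sweep (the acknowledged source of run-to-run
#' instability of modularity maximization, reproducible here through
#' `seed`), single-node moves accepted only for gains above `tol`, ties
#' resolved by keeping the current community (else the lowest candidate
#' label), then aggregation of communities into super-nodes with
#' self-loops, repeated until no merge occurs. Isolated nodes end up as
#' singleton communities. An edgeless network yields all singletons.
#'
#' @param network a [weighted_network()].
#' @param gamma resolution parameter (> 0).
#' @param seed integer seed; same seed, same partition.
#' @param max_passes cap on aggregation levels (guards cycling).
#' @param tol minimum gain for a move (on the unnormalized Q scale).
#' @return a [partition()] with labels `1..k` in order of first node
#'   appearance.
#' @export
louvain_optimize <- function(network, gamma = 1, seed = 1L, max_passes = 50L,
                             tol = 1e-12) {
  stopifnot(is_weighted_network(network), gamma > 0)
  if (n_nodes(network) == 0) stop("empty network")
  lab <- cpp_louvain(network$weights, gamma, as.integer(seed),
                     as.integer(max_passes), tol)
  partition(lab, network$node_ids)
}
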