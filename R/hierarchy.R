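#' Pairwise Euclidean distance matrix of node attributes
#'
#' @param attributes a [node_attributes()] table (`N x m`).
#' @return symmetric `N x N` matrix, zero diagonal, node-id dimnames.
#' @export
distance_matrix <- function(attributes) {
  stopifnot(inherits(attributes, "node_attributes"))
  D <- as.matrix(dist(attributes$values))
  dimnames(D) <- list(attributes$node_ids, attributes$node_ids)
  D
}

#' Mean spatial distance of a community
#'
#' \eqn{d = N_c^{-2} \sum_i \sum_j D_{ij}} over the community's nodes, zero
#' diagonal included, per the printed formula; a singleton community has
#' `d = 0`. (The off-diagonal mean would use `1/(N_c (N_c - 1))`; the
#' permutation null uses the same formula, so the choice cancels in the
#' subdivision test.)
#'
#' @param nodes character vector of node ids (non-empty).
#' @param D full distance matrix with node-id dimnames.
#' @return scalar `d >= 0`.
#' @export
community_distance <- function(nodes, D) {
  nodes <- as.character(nodes)
  if (!length(nodes)) stop("empty community")
  if (!all(nodes %in% rownames(D))) stop("nodes missing from distance matrix")
  sub <- D[nodes, nodes, drop = FALSE]
  sum(sub) / length(nodes)^2
}

#' Post-subdivision spatial distance
#'
#' Unweighted mean of [community_distance()] over the sub-communities of a
#' partition of one community. With a single sub-community it equals the
#' community's own distance.
#'
#' @param sub_partition a [partition()] over the community's nodes.
#' @param D full distance matrix.
#' @return scalar `d'`.
#' @export
post_subdivision_distance <- function(sub_partition, D) {
  if (!is_partition(sub_partition)) sub_partition <- partition(sub_partition)
  groups <- split(names(sub_partition), as.integer(sub_partition))
  mean(vapply(groups, community_distance, numeric(1), D = D))
}

#' Permutation test for community subdivision
#'
#' Tests whether a proposed subdivision of a community reduces its mean
#' spatial distance beyond chance. Node-to-subcommunity assignments are
#' shuffled `n_perm` times with the sub-community sizes and count fixed
#' (nodes outside the community never enter the null); the subdivision is
#' accepted iff `d_after < d_before` and `d_after` is smaller than the
#' `ceiling(n_perm * alpha)`-th smallest null distance.
#'
#' @param sub_partition a [partition()] over the community's nodes with at
#'   least 2 sub-communities.
#' @param D full distance matrix covering those nodes.
#' @param n_perm number of shuffles T (paper-default 10000).
#' @param alpha significance level (default 0.05); `n_perm * alpha` must be
#'   at least 1.
#' @param seed integer seed for the shuffles.
#' @return list with `d_before`, `d_after`, `null_quantile`,
#'   `empirical_quantile` (fraction of null values strictly below
#'   `d_after`) and `accepted`.
#' @export
permutation_test <- function(sub_partition, D, n_perm = 10000L, alpha = 0.05,
                             seed = 1L) {
  if (!is_partition(sub_partition)) sub_partition <- partition(sub_partition)
  if (n_communities(sub_partition) < 2)
    stop("sub_partition must have at least 2 sub-communities")
  if (n_perm * alpha < 1) stop("n_perm * alpha < 1: null quantile undefined")
  nodes <- names(sub_partition)
  Dsub <- D[nodes, nodes, drop = FALSE]
  d_before <- community_distance(nodes, D)
  d_after <- post_subdivision_distance(sub_partition, D)
  sizes <- as.integer(community_sizes(sub_partition))
  nulls <- cpp_perm_null(Dsub, sizes, as.integer(n_perm), as.integer(seed))
  nulls <- sort(nulls)
  thr <- nulls[ceiling(n_perm * alpha)]
  list(d_before = d_before,
       d_after = d_after,
       null_quantile = thr,
       empirical_quantile = mean(nulls < d_after),
       accepted = (d_after < d_before) && (d_after < thr))
}

#' Two-step WMM: hierarchical community detection with a spatial gate
#'
#' Step one runs [wmm()] on the full network. Step two reruns WMM on the
#' induced subnetwork of every first-step community of at least
#' `min_subdivide_size` nodes and keeps the subdivision only when the
#' spatial [permutation_test()] on the node attributes accepts it. A
#' community whose second-step WMM returns a single community is retained
#' untested. Retained communities keep their level-1 labels; accepted
#' subdivisions receive fresh globally unique labels.
#'
#' @param network a [weighted_network()].
#' @param attributes a [node_attributes()] table covering all nodes (for
#'   brain networks: 3-D region coordinates).
#' @param n_perm permutation count T (default 10000).
#' @param alpha significance level (default 0.05).
#' @param min_subdivide_size smallest community eligible for subdivision
#'   (default 6).
#' @param pool_size,n_selected,n_selections,gamma WMM configuration reused
#'   by both steps (see [wmm()]).
#' @param seed root seed.
#' @return object of class `hierarchical_partition`: list with `level1`,
#'   `level2` (both [partition()]), `provenance` (level-2 label ->
#'   parent level-1 label) and `test_results` (one record per level-1
#'   community).
#' @export
two_step_wmm <- function(network, attributes, n_perm = 10000L, alpha = 0.05,
                         min_subdivide_size = 6L, pool_size = 100L,
                         n_selected = 50L, n_selections = 50L, gamma = 1,
                         seed = 1L) {
  stopifnot(is_weighted_network(network),
            inherits(attributes, "node_attributes"))
  if (!setequal(attributes$node_ids, network$node_ids))
    stop("attributes must cover exactly the network's nodes")
  if (total_weight(network) <= 0) stop("empty network: 2U = 0")

  D <- distance_matrix(attributes)
  s <- spawn_seeds(seed, 2)
  level1 <- wmm(network, pool_size, n_selected, n_selections, gamma,
                seed = s[1])
  comms <- sort(unique(as.integer(level1)))
  sub_seeds <- spawn_seeds(s[2], 2L * length(comms))

  level2 <- as.integer(level1)
  names(level2) <- names(level1)
  next_label <- max(as.integer(level1)) + 1L
  provenance <- list()
  test_results <- list()

  for (ci in seq_along(comms)) {
    cl <- comms[ci]
    members <- names(level1)[as.integer(level1) == cl]
    rec <- list(community = cl, size = length(members), tested = FALSE,
                accepted = FALSE, d_before = NA_real_, d_after = NA_real_,
                null_quantile = NA_real_, empirical_quantile = NA_real_)
    if (length(members) >= min_subdivide_size) {
      subnet <- induced_subnetwork(network, members)
      sub <- if (total_weight(subnet) > 0)
        wmm(subnet, pool_size, n_selected, n_selections, gamma,
            seed = sub_seeds[2 * ci - 1])
      else partition(seq_along(members), members)
      if (n_communities(sub) >= 2) {
        tr <- permutation_test(sub, D, n_perm = n_perm, alpha = alpha,
                               seed = sub_seeds[2 * ci])
        rec$tested <- TRUE
        rec[c("d_before", "d_after", "null_quantile",
              "empirical_quantile", "accepted")] <-
          tr[c("d_before", "d_after", "null_quantile",
               "empirical_quantile", "accepted")]
        if (tr$accepted) {
          sub_labels <- as.integer(sub)
          for (sl in sort(unique(sub_labels))) {
            nn <- names(sub)[sub_labels == sl]
            level2[nn] <- next_label
            provenance[[as.character(next_label)]] <- cl
            next_label <- next_label + 1L
          }
        }
      }
    }
    if (!isTRUE(rec$accepted))
      provenance[[as.character(cl)]] <- cl
    test_results[[as.character(cl)]] <- rec
  }

  structure(list(level1 = level1,
                 level2 = partition(level2),
                 provenance = unlist(provenance),
                 test_results = test_results),
            class = "hierarchical_partition")
}

#' @export
print.hierarchical_partition <- function(x, ...) {
  acc <- sum(vapply(x$test_results, function(r) isTRUE(r$accepted),
                    logical(1)))
  cat(sprintf(paste0("<hierarchical_partition> level 1: %d communities; ",
                     "level 2: %d communities (%d subdivision%s accepted)\n"),
              n_communities(x$level1), n_communities(x$level2), acc,
              if (acc == 1) "" else "s"))
  invisible(x)
}

#' Write a hierarchical partition as TSV (`node_id  level1  level2`)
#' @param hp a `hierarchical_partition`.
#' @param path output path.
#' @export
write_hierarchical_partition <- function(hp, path) {
  stopifnot(inherits(hp, "hierarchical_partition"))
  ids <- names(hp$level1)
  df <- data.frame(id = ids, level1 = as.integer(hp$level1),
                   level2 = as.integer(hp$level2)[match(ids, names(hp$level2))])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
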