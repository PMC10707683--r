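#' Benchmark specification for weighted planted-partition networks
#'
#' Parameters of an LFR-style weighted benchmark: node degrees follow a
#' truncated power law (exponent `tau1`, mean `mean_degree`, cap
#' `max_degree`), community sizes a power law (exponent `tau2`), node
#' strengths scale as `degree^beta`, and `mu_t` / `mu_w` set the expected
#' fraction of each node's degree / strength that crosses community
#' boundaries (the benchmark's noise level).
#'
#' @param n_nodes network size N.
#' @param mean_degree target average degree.
#' @param max_degree degree cap.
#' @param mu_t topological mixing in `[0, 1)`.
#' @param mu_w strength mixing (defaults to `mu_t`, as in the simulation
#'   design where both are varied together).
#' @param tau1 degree exponent (default 2).
#' @param tau2 community-size exponent (default 1).
#' @param beta strength exponent (default 1.5).
#' @param seed integer seed.
#' @return object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_nodes, mean_degree, max_degree, mu_t,
                           mu_w = mu_t, tau1 = 2, tau2 = 1, beta = 1.5,
                           seed = 1L) {
  stopifnot(n_nodes >= 2, mean_degree <= max_degree, max_degree < n_nodes,
            mu_t >= 0, mu_t < 1, mu_w >= 0, mu_w < 1)
  structure(list(n_nodes = as.integer(n_nodes), mean_degree = mean_degree,
                 max_degree = as.integer(max_degree), mu_t = mu_t,
                 mu_w = mu_w, tau1 = tau1, tau2 = tau2, beta = beta,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' @rdname benchmark_spec
#' @param n_attributes number of continuous node attributes (default 3).
#' @param attribute_sd Gaussian attribute noise around each community's
#'   center (centers are unit-separated), `> 0`.
#' @param ... passed to [benchmark_spec()].
#' @export
attributed_benchmark_spec <- function(..., n_attributes = 3L,
                                      attribute_sd = 0.2) {
  spec <- benchmark_spec(...)
  stopifnot(attribute_sd > 0, n_attributes >= 1)
  spec$n_attributes <- as.integer(n_attributes)
  spec$attribute_sd <- attribute_sd
  class(spec) <- c("attributed_benchmark_spec", "benchmark_spec")
  spec
}

# mean of a continuous truncated power law x^-tau on [a, b]
powerlaw_mean <- function(a, b, tau) {
  if (abs(tau - 1) < 1e-9) {
    (b - a) / log(b / a)
  } else if (abs(tau - 2) < 1e-9) {
    log(b / a) / (1 / a - 1 / b)
  } else {
    ((b^(2 - tau) - a^(2 - tau)) / (2 - tau)) /
      ((b^(1 - tau) - a^(1 - tau)) / (1 - tau))
  }
}

# inverse-CDF sampling from a continuous truncated power law
rplaw <- function(n, a, b, tau) {
  u <- runif(n)
  if (abs(tau - 1) < 1e-9) {
    a * (b / a)^u
  } else {
    (a^(1 - tau) + u * (b^(1 - tau) - a^(1 - tau)))^(1 / (1 - tau))
  }
}

# degree sequence: solve for the lower cutoff so the continuous power law
# has the target mean, sample, round, clamp
sample_degrees <- function(n, mean_degree, max_degree, tau1) {
  f <- function(a) powerlaw_mean(a, max_degree, tau1) - mean_degree
  lo <- 1; hi <- max_degree - 1e-6
  a <- if (f(lo) >= 0) lo else uniroot(f, c(lo, hi))$root
  k <- pmin(max_degree, pmax(1L, as.integer(round(rplaw(n, a, max_degree,
                                                        tau1)))))
  as.integer(k)
}

# community sizes from a power law, minimally adjusted to sum to N with
# every size in [cmin, cmax]
sample_community_sizes <- function(n, cmin, cmax, tau2) {
  cmin <- min(cmin, n)
  cmax <- min(cmax, n)
  if (cmin > cmax) cmin <- cmax
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, max(cmin, min(cmax, round(rplaw(1, cmin, cmax, tau2)))))
  excess <- sum(sizes) - n
  guard <- 0
  while (excess > 0 && guard < 10000) {
    i <- which.max(sizes)
    take <- min(excess, sizes[i] - cmin)
    if (take > 0) {
      sizes[i] <- sizes[i] - take
      excess <- excess - take
    } else {
      # all at cmin: drop the last community, redistribute the deficit
      sizes <- sizes[-length(sizes)]
      excess <- sum(sizes) - n
      while (excess < 0) {
        j <- which.min(sizes)
        add <- min(-excess, cmax - sizes[j])
        if (add <= 0) break
        sizes[j] <- sizes[j] + add
        excess <- excess + add
      }
    }
    guard <- guard + 1
  }
  if (sum(sizes) != n) stop("infeasible community-size specification")
  as.integer(sizes)
}

# Chung-Lu style Bernoulli wiring: edge probability proportional to the
# product of the endpoints' target (internal or external) degrees, so each
# node's expected degree of either kind matches its target without the
# collision losses of stub matching.
# A few proportional-fitting rounds correct the self-exclusion bias
# (E[deg_i] = k_i - k_i^2/tot under plain Chung-Lu) and probability
# clamping, which matter in small dense communities.
chung_lu_block <- function(target, allowed) {
  n <- length(target)
  if (sum(target) <= 0 || n < 2) return(matrix(0, n, n))
  w <- target
  P <- NULL
  for (it in 1:12) {
    P <- pmin(outer(w, w) / sum(w), 1)
    P[!allowed] <- 0
    diag(P) <- 0
    expected <- rowSums(P)
    ratio <- ifelse(target > 0 & expected > 0, target / expected, 1)
    w <- w * pmin(ratio, 2)
  }
  U <- matrix(runif(n * n), n, n)
  U[lower.tri(U)] <- t(U)[lower.tri(U)]
  (U < P) * 1L
}

#' Generate a weighted planted-partition benchmark network
#'
#' Emulates the statistical structure of the LFR weighted benchmark rather
#' than porting its rewiring loop: power-law degrees and community sizes,
#' stub-matching wiring targeting an expected inter-community degree
#' fraction `mu_t`, and per-node strength budgets `k^beta` split
#' `(1 - mu_w)` within / `mu_w` between communities, spread equally over a
#' node's incident edges of each kind and symmetrized by averaging the two
#' endpoint contributions. At `mu_t = 0` the communities are disconnected
#' components.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `network` (a [weighted_network()]) and `partition`
#'   (the planted ground truth).
#' @export
generate_weighted_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, generate_benchmark_impl(spec, weighted = TRUE))
}

generate_benchmark_impl <- function(spec, weighted) {
  n <- spec$n_nodes
  deg <- sample_degrees(n, spec$mean_degree, spec$max_degree, spec$tau1)
  int_deg <- as.integer(round((1 - spec$mu_t) * deg))
  cmin <- max(2L, min(int_deg) + 1L)
  cmax <- max(min(n, spec$max_degree), max(int_deg) + 1L)
  cmax <- min(cmax, n)
  sizes <- sample_community_sizes(n, cmin, cmax, spec$tau2)
  q <- length(sizes)
  if (q < 2 && spec$mu_t > 0)
    stop("infeasible spec: a single community cannot carry mixing > 0")

  # assign high-internal-degree nodes first; cap where capacity runs short
  comm <- integer(n)
  remaining <- sizes
  ord <- order(-int_deg)
  for (i in ord) {
    elig <- which(remaining > 0 & sizes - 1L >= int_deg[i])
    c_i <- if (length(elig)) elig[sample.int(length(elig), 1)] else
      which.max(remaining)
    comm[i] <- c_i
    remaining[c_i] <- remaining[c_i] - 1L
  }
  int_deg <- pmin(int_deg, sizes[comm] - 1L)
  ext_deg <- deg - int_deg

  A <- matrix(0, n, n)
  for (cc in seq_len(q)) {
    members <- which(comm == cc)
    if (length(members) >= 2) {
      blk <- chung_lu_block(int_deg[members],
                            matrix(TRUE, length(members), length(members)))
      A[members, members] <- blk
    }
  }
  if (spec$mu_t > 0 && sum(ext_deg) > 0) {
    cross <- outer(comm, comm, "!=")
    A <- pmax(A, chung_lu_block(ext_deg, cross))
  }

  if (weighted) {
    s_budget <- deg^spec$beta
    internal_edge <- outer(comm, comm, "==")
    n_int <- rowSums(A * internal_edge)
    n_ext <- rowSums(A * !internal_edge)
    contr_int <- ifelse(n_int > 0, (1 - spec$mu_w) * s_budget / n_int, 0)
    contr_ext <- ifelse(n_ext > 0, spec$mu_w * s_budget / n_ext, 0)
    Wmat <- matrix(0, n, n)
    idx <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(idx)) {
      i <- idx[, 1]; j <- idx[, 2]
      same <- comm[i] == comm[j]
      w <- ifelse(same, (contr_int[i] + contr_int[j]) / 2,
                  (contr_ext[i] + contr_ext[j]) / 2)
      Wmat[idx] <- w
      Wmat[idx[, c(2, 1), drop = FALSE]] <- w
    }
    A <- Wmat
  }

  ids <- as.character(seq_len(n))
  list(network = weighted_network(A, ids),
       partition = partition(comm, ids),
       sizes = sizes)
}

#' Generate an attributed planted-partition benchmark
#'
#' Unweighted (0/1) planted-partition network with `n_attributes`
#' continuous node attributes: every community owns a distinct center on a
#' unit-spaced integer grid (inter-center distance >= 1) and node
#' attributes are the center plus isotropic Gaussian noise of standard
#' deviation `attribute_sd`, so `attribute_sd` directly controls cluster
#' overlap.
#'
#' @param spec an [attributed_benchmark_spec()].
#' @return list with `network`, `attributes` (a [node_attributes()]) and
#'   `partition`.
#' @export
generate_attributed_benchmark <- function(spec) {
  stopifnot(inherits(spec, "attributed_benchmark_spec"))
  with_seed(spec$seed, {
    out <- generate_benchmark_impl(spec, weighted = FALSE)
    q <- length(out$sizes)
    centers <- grid_centers(q, spec$n_attributes)
    comm <- as.integer(out$partition)
    n <- length(comm)
    vals <- centers[comm, , drop = FALSE] +
      matrix(rnorm(n * spec$n_attributes, 0, spec$attribute_sd), n)
    out$attributes <- node_attributes(vals, names(out$partition))
    out[c("network", "attributes", "partition")]
  })
}

# first q points of an m-dimensional unit-spaced integer grid
grid_centers <- function(q, m) {
  g <- ceiling(q^(1 / m))
  pts <- as.matrix(do.call(expand.grid, rep(list(seq_len(g) - 1), m)))
  unname(pts[seq_len(q), , drop = FALSE]) * 1.0
}

#' Generate a nested (two-level) planted-hierarchy fixture
#'
#' Stochastic block model with `n_super` super-communities of
#' `n_sub_per_super` sub-blocks each (`sub_size` nodes per sub-block) and
#' edge probabilities `p_in_sub > p_in_super > p_out`. Sub-blocks within a
#' super-community sit at spatially separated centers (pairwise center
#' distance `spatial_sep`, Gaussian spread `sigma`); super-communities are
#' placed far apart. Both truth levels are returned, making this the
#' canonical test bed for the two-step subdivision gate.
#'
#' @param n_super,n_sub_per_super,sub_size block design.
#' @param p_in_sub,p_in_super,p_out edge probabilities (must be strictly
#'   decreasing in that order).
#' @param spatial_sep center separation of sibling sub-blocks (0 = no
#'   spatial signal).
#' @param sigma attribute noise around each sub-block center.
#' @param seed integer seed.
#' @return list with `network`, `attributes`, `level1`, `level2`.
#' @export
generate_hierarchical_fixture <- function(n_super = 2L, n_sub_per_super = 2L,
                                          sub_size = 25L, p_in_sub = 0.8,
                                          p_in_super = 0.3, p_out = 0.02,
                                          spatial_sep = 5, sigma = 0.5,
                                          seed = 1L) {
  stopifnot(p_in_sub > p_in_super, p_in_super > p_out, p_out >= 0,
            p_in_sub <= 1)
  with_seed(seed, {
    n <- n_super * n_sub_per_super * sub_size
    super <- rep(seq_len(n_super), each = n_sub_per_super * sub_size)
    sub <- rep(seq_len(n_super * n_sub_per_super), each = sub_size)
    P <- matrix(p_out, n, n)
    same_super <- outer(super, super, "==")
    same_sub <- outer(sub, sub, "==")
    P[same_super] <- p_in_super
    P[same_sub] <- p_in_sub
    U <- matrix(runif(n * n), n, n)
    U[lower.tri(U)] <- t(U)[lower.tri(U)]
    A <- (U < P) * 1.0
    diag(A) <- 0

    super_gap <- max(10 * spatial_sep, 10)
    sub_centers <- matrix(0, n_super * n_sub_per_super, 3)
    for (s in seq_len(n_super)) {
      base <- c((s - 1) * super_gap, 0, 0)
      local <- grid_centers(n_sub_per_super, 3) * spatial_sep
      rows <- (s - 1) * n_sub_per_super + seq_len(n_sub_per_super)
      sub_centers[rows, ] <- sweep(local, 2, base, "+")
    }
    vals <- sub_centers[sub, , drop = FALSE] + matrix(rnorm(3 * n, 0, sigma),
                                                      n)
    ids <- as.character(seq_len(n))
    list(network = weighted_network(A, ids),
         attributes = node_attributes(vals, ids),
         level1 = partition(super, ids),
         level2 = partition(sub, ids))
  })
}

#' Enumerate the simulation-study parameter grid
#'
#' The five-row benchmark design (network sizes 50/100/300/500/1000 with
#' matched degree parameters and mixing ranges; the smallest size stops at
#' `mu = 0.7`) enumerates to 28 parameter combinations; with the study's
#' 50 networks per combination, 1400 specs. Ordering is deterministic:
#' size ascending, then `mu` ascending, then replicate.
#'
#' @param replicates networks per parameter combination (default 1).
#' @param seed root seed from which each spec's generator seed is derived.
#' @return list of [benchmark_spec()]s of length `28 * replicates`.
#' @export
experiment_grid <- function(replicates = 1L, seed = 1L) {
  rows <- list(
    list(n = 50L,   k = 3,  maxk = 9L,   mus = seq(0.2, 0.7, by = 0.1)),
    list(n = 100L,  k = 5,  maxk = 25L,  mus = seq(0.2, 0.8, by = 0.1)),
    list(n = 300L,  k = 15, maxk = 75L,  mus = seq(0.4, 0.8, by = 0.1)),
    list(n = 500L,  k = 25, maxk = 125L, mus = seq(0.4, 0.8, by = 0.1)),
    list(n = 1000L, k = 50, maxk = 250L, mus = seq(0.4, 0.8, by = 0.1)))
  combos <- list()
  for (r in rows)
    for (mu in r$mus)
      combos[[length(combos) + 1L]] <- list(n = r$n, k = r$k, maxk = r$maxk,
                                            mu = round(mu, 10))
  seeds <- spawn_seeds(seed, length(combos) * replicates)
  out <- vector("list", length(combos) * replicates)
  idx <- 1L
  for (cb in combos) {
    for (rep in seq_len(replicates)) {
      out[[idx]] <- benchmark_spec(cb$n, cb$k, cb$maxk, cb$mu,
                                   tau1 = 2, tau2 = 1, beta = 1.5,
                                   seed = seeds[idx])
      idx <- idx + 1L
    }
  }
  out
}
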