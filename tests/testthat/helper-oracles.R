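# Independent oracles and shared fixtures. The oracles are deliberately
# plain-loop implementations kept free of the package's own code paths.

# all set partitions of n items as restricted-growth label vectors
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxlab + 1L)) rec(c(prefix, l), max(maxlab, l))
  }
  rec(integer(0), 0L)
  out
}

# brute-force double-sum modularity (unnormalized, ordered pairs incl i=j)
oracle_modularity <- function(A, lab, gamma = 1) {
  n <- nrow(A)
  twoU <- sum(A)
  k <- unname(rowSums(A))
  Q <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (lab[i] == lab[j]) Q <- Q + A[i, j] - gamma * k[i] * k[j] / twoU
  Q
}

# contingency-table NMI computed with explicit loops
oracle_nmi <- function(xlab, ylab) {
  n <- length(xlab)
  xs <- unique(xlab)
  ys <- unique(ylab)
  hx <- 0
  for (a in xs) {
    p <- sum(xlab == a) / n
    hx <- hx - p * log(p)
  }
  hy <- 0
  for (b in ys) {
    p <- sum(ylab == b) / n
    hy <- hy - p * log(p)
  }
  if (hx + hy == 0) return(1)
  mi <- 0
  for (a in xs)
    for (b in ys) {
      pab <- sum(xlab == a & ylab == b) / n
      if (pab > 0) {
        pa <- sum(xlab == a) / n
        pb <- sum(ylab == b) / n
        mi <- mi + pab * log(pab / (pa * pb))
      }
    }
  2 * mi / (hx + hy)
}

# connected components by BFS on an adjacency matrix
oracle_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# --- fixtures -------------------------------------------------------------

# two unit-weight triangles, optionally joined by one bridge edge (3-4)
make_two_triangles <- function(bridge = FALSE) {
  A <- matrix(0, 6, 6)
  e <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  if (bridge) e <- rbind(e, c(3, 4))
  A[e] <- 1
  A[e[, c(2, 1)]] <- 1
  weighted_network(A)
}

# Erdos-Renyi-ish random weighted network (guaranteed at least one edge)
random_weighted_network <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[runif(length(up)) < p]
    if (length(on)) break
  }
  A[on] <- round(runif(length(on), 0.1, 2), 6)
  A <- A + t(A)
  weighted_network(A)
}

random_labels <- function(n, kmax = 4) sample.int(kmax, n, replace = TRUE)
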