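#' Normalized mutual information between two partitions
#'
#' \deqn{NMI(X, Y) = 2\,MI(X, Y) / (H(X) + H(Y))}
#' where `H` is the Shannon entropy of the community-size distribution and
#' `MI` the mutual information of the joint contingency table. Ranges from
#' 0 (independent partitions) to 1 (identical up to relabeling);
#' symmetric and invariant to label permutations of either argument.
#' Degenerate case: if both partitions are trivial single-community
#' (`H(X) + H(Y) = 0`) they are identical and NMI is defined as 1.
#'
#' @param x,y [partition()]s over the same node set.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  if (!is_partition(x)) x <- partition(x)
  if (!is_partition(y)) y <- partition(y)
  if (!setequal(names(x), names(y)))
    stop("partitions cover different node sets")
  ylab <- as.integer(y)[match(names(x), names(y))]
  xlab <- as.integer(x)
  n <- length(xlab)
  joint <- table(xlab, ylab) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  if (hx + hy == 0) return(1)
  outerp <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outerp[nz]))
  2 * mi / (hx + hy)
}

#' Match community labels against a reference partition
#'
#' Relabels `p` so its communities carry the labels of the reference
#' communities they overlap most. Matching is greedy in descending overlap
#' size; ties go to the smallest reference label, then the smallest
#' partition label. Communities left unmatched receive fresh labels above
#' the reference's maximum. `method = "optimal"` solves the assignment
#' exactly by exhaustive permutation (only for <= 9 communities; a
#' sensitivity check, not the default).
#'
#' @param p the [partition()] to relabel.
#' @param reference the reference [partition()] (same node set).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return relabeled [partition()] in the node order of `p`.
#' @export
match_labels <- function(p, reference, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!is_partition(p)) p <- partition(p)
  if (!is_partition(reference)) reference <- partition(reference)
  if (!setequal(names(p), names(reference)))
    stop("partitions cover different node sets")
  rlab <- as.integer(reference)[match(names(p), names(reference))]
  plab <- as.integer(p)
  pu <- sort(unique(plab))
  ru <- sort(unique(rlab))
  O <- table(factor(plab, levels = pu), factor(rlab, levels = ru))
  O <- matrix(as.numeric(O), nrow = length(pu), ncol = length(ru))

  assign_to <- rep(NA_integer_, length(pu))  # index into ru
  if (method == "greedy") {
    Ow <- O
    repeat {
      mx <- max(Ow)
      if (mx <= 0) break
      hits <- which(Ow == mx, arr.ind = TRUE)
      # ties: smallest reference label, then smallest partition label
      hits <- hits[order(ru[hits[, 2]], pu[hits[, 1]]), , drop = FALSE]
      i <- hits[1, 1]; j <- hits[1, 2]
      assign_to[i] <- j
      Ow[i, ] <- -1
      Ow[, j] <- -1
    }
  } else {
    k <- max(length(pu), length(ru))
    if (k > 9) stop("optimal matching supported only for <= 9 communities")
    Opad <- matrix(0, k, k)
    Opad[seq_along(pu), seq_along(ru)] <- O
    best <- NULL; best_val <- -Inf
    for (perm in all_permutations(k)) {
      v <- sum(Opad[cbind(seq_len(k), perm)])
      if (v > best_val) { best_val <- v; best <- perm }
    }
    assign_to <- ifelse(best[seq_along(pu)] <= length(ru),
                        best[seq_along(pu)], NA_integer_)
    # drop padded assignments with zero overlap
    real <- !is.na(assign_to)
    zero <- real & O[cbind(seq_along(pu), ifelse(real, assign_to, 1))] == 0
    assign_to[zero] <- NA_integer_
  }

  new_of <- integer(length(pu))
  fresh <- max(ru) + 1L
  for (i in seq_along(pu)) {
    if (!is.na(assign_to[i])) {
      new_of[i] <- ru[assign_to[i]]
    } else {
      new_of[i] <- fresh
      fresh <- fresh + 1L
    }
  }
  partition(new_of[match(plab, pu)], names(p))
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_permutations(k - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, ifelse(r >= i, r + 1L, r))
  }
  out
}

#' Average node entropy of a partition ensemble
#'
#' Stability index of repeated community detection: every ensemble member
#' is label-matched against the chosen reference member, then each node's
#' Shannon entropy (base 2) of its matched labels across the ensemble is
#' computed and averaged over nodes. Zero for a perfectly stable ensemble;
#' invariant to global label permutations of any member.
#'
#' @param ensemble a [partition_ensemble()] of size >= 2.
#' @param reference_index which member serves as the label reference.
#' @param method label-matching method (see [match_labels()]).
#' @return scalar mean entropy in bits.
#' @export
average_node_entropy <- function(ensemble, reference_index = 1L,
                                 method = "greedy") {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  if (ensemble$size < 2) stop("ensemble must contain at least 2 partitions")
  ref <- ensemble$partitions[[reference_index]]
  matched <- vapply(ensemble$partitions, function(p)
    as.integer(match_labels(p, ref, method = method)),
    integer(length(ref)))
  # matched: nodes x members
  ent <- apply(matched, 1, function(lv) {
    f <- tabulate(factor(lv)) / length(lv)
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  mean(ent)
}

#' Mean average node entropy over all reference choices
#'
#' [average_node_entropy()] depends mildly on which member anchors the
#' label matching; the reported stability index averages it over every
#' choice of reference. This is the per-network stability value used in
#' the method comparisons (lower = more stable).
#'
#' @param ensemble a [partition_ensemble()] of size >= 2.
#' @param method label-matching method.
#' @return scalar mean entropy in bits.
#' @export
mean_average_node_entropy <- function(ensemble, method = "greedy") {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  if (ensemble$size < 2) stop("ensemble must contain at least 2 partitions")
  mean(vapply(seq_len(ensemble$size), function(i)
    average_node_entropy(ensemble, i, method = method), numeric(1)))
}
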