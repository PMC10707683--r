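#' Weighted network
#'
#' An undirected weighted network over `N` labeled nodes, stored as a dense
#' symmetric non-negative adjacency matrix `A` with zero diagonal (no
#' self-loops). Node ids are arbitrary strings; the matrix row/column order
#' is the canonical internal node order used by every other structure in
#' the package (partitions, attribute tables, weight matrices).
#'
#' @param weights square numeric matrix, symmetric, non-negative, zero
#'   diagonal.
#' @param node_ids optional character vector of node labels; defaults to
#'   the matrix dimnames or `"1".."N"`.
#' @return an object of class `weighted_network` with elements `node_ids`
#'   and `weights`.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1.5
#' net <- weighted_network(A, c("a", "b", "c"))
#' strengths(net)
#' @export
weighted_network <- function(weights, node_ids = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be a square matrix")
  if (is.null(node_ids)) {
    node_ids <- rownames(weights)
    if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(weights)))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(weights)) stop("node_ids length mismatch")
  if (anyDuplicated(node_ids)) stop("duplicate node ids")
  if (any(!is.finite(weights))) stop("non-finite edge weights")
  if (any(weights < 0)) stop("negative edge weights are not allowed")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-10,
                        check.attributes = FALSE)))
    stop("weights must be symmetric")
  if (any(abs(diag(weights)) > 0)) stop("diagonal must be zero (no self-loops)")
  weights <- (weights + t(weights)) / 2  # exact symmetry
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, weights = weights),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights > 0) / 2
  cat(sprintf("<weighted_network> %d nodes, %d edges, total weight 2U = %g\n",
              length(x$node_ids), m, sum(x$weights)))
  invisible(x)
}

#' @rdname weighted_network
#' @param x object to test.
#' @export
is_weighted_network <- function(x) inherits(x, "weighted_network")

#' Number of nodes of a network
#' @param network a [weighted_network()].
#' @export
n_nodes <- function(network) length(network$node_ids)

#' Node strengths
#'
#' The strength of node `i` is \eqn{k_i = \sum_j A_{ij}}; strengths sum to
#' `2U`, twice the total edge weight.
#'
#' @param network a [weighted_network()].
#' @return named numeric vector of length `N`.
#' @export
strengths <- function(network) {
  stopifnot(is_weighted_network(network))
  rowSums(network$weights)
}

#' Total edge weight (2U)
#' @param network a [weighted_network()].
#' @return \eqn{2U = \sum_{ij} A_{ij}}.
#' @export
total_weight <- function(network) sum(network$weights)

#' Subnetwork induced by a node subset
#'
#' Keeps exactly the within-subset edges; node order within the subset is
#' preserved from the parent network.
#'
#' @param network a [weighted_network()].
#' @param nodes character vector of node ids (subset of the network's).
#' @export
induced_subnetwork <- function(network, nodes) {
  stopifnot(is_weighted_network(network))
  nodes <- as.character(nodes)
  unknown <- setdiff(nodes, network$node_ids)
  if (length(unknown))
    stop("unknown node id(s): ", paste(head(unknown, 5), collapse = ", "))
  keep <- network$node_ids[network$node_ids %in% nodes]
  weighted_network(network$weights[keep, keep, drop = FALSE], keep)
}

#' Read an undirected weighted edge list
#'
#' Whitespace/tab-delimited lines `node_i node_j [weight]`; a missing third
#' column defaults to weight 1. Each undirected edge may appear once or
#' twice; duplicate entries must carry the same weight. Self-loop rows are
#' dropped with a warning. With `n_nodes` given (integer node ids assumed
#' `1..n_nodes`), nodes absent from the file are included as isolated.
#'
#' @param path file path.
#' @param n_nodes optional total node count for isolated-node padding.
#' @return a [weighted_network()].
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  df <- read.table(path, header = FALSE, colClasses = "character",
                   fill = TRUE, blank.lines.skip = TRUE)
  if (ncol(df) < 2) stop("edge list needs at least two columns")
  if (ncol(df) >= 3) {
    w <- suppressWarnings(as.numeric(df[[3]]))
    w[df[[3]] == ""] <- 1.0  # rows without the optional weight field
  } else {
    w <- rep(1.0, nrow(df))
  }
  if (any(is.na(w))) stop("non-numeric weight entries")
  if (any(w < 0)) stop("negative edge weights are not allowed")
  a <- df[[1]]; b <- df[[2]]
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop entr", if (sum(self) == 1) "y" else "ies",
            " dropped")
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (!is.null(n_nodes)) {
    ids <- as.character(seq_len(n_nodes))
    if (!all(c(a, b) %in% ids))
      stop("edge list references node ids outside 1..n_nodes")
  } else {
    ids <- unique(c(rbind(a, b)))  # order of first appearance
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(a, ids); ib <- match(b, ids)
  # canonical key per undirected pair to detect conflicting duplicates
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  for (kk in unique(key)) {
    sel <- key == kk
    ww <- unique(w[sel])
    if (length(ww) > 1)
      stop("conflicting duplicate weights for edge ", a[sel][1], "-", b[sel][1])
  }
  A[cbind(ia, ib)] <- w
  A[cbind(ib, ia)] <- w
  weighted_network(A, ids)
}

#' Write an edge list
#'
#' One row per undirected edge with nonzero weight, `i < j` in internal
#' node order, tab-separated: `node_i  node_j  weight`.
#'
#' @param network a [weighted_network()].
#' @param path output file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(is_weighted_network(network))
  A <- network$weights
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(i = network$node_ids[idx[, 1]],
                   j = network$node_ids[idx[, 2]],
                   w = format(A[idx], digits = 17, scientific = FALSE,
                              trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Node attribute table
#'
#' `N x m` matrix of continuous node attributes (e.g. 3-D spatial
#' coordinates of brain regions); row order must match the network's node
#' order.
#'
#' @param values numeric matrix (`N x m`).
#' @param node_ids character node labels (length `N`).
#' @param attribute_names optional column labels.
#' @export
node_attributes <- function(values, node_ids = NULL, attribute_names = NULL) {
  values <- as.matrix(values)
  if (is.null(node_ids)) node_ids <- rownames(values)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(values)))
  if (length(node_ids) != nrow(values)) stop("node_ids length mismatch")
  if (is.null(attribute_names)) {
    attribute_names <- colnames(values)
    if (is.null(attribute_names))
      attribute_names <- paste0("attr", seq_len(ncol(values)))
  }
  if (any(!is.finite(values))) stop("non-finite attribute values")
  dimnames(values) <- list(as.character(node_ids), attribute_names)
  structure(list(values = values, node_ids = as.character(node_ids),
                 attribute_names = attribute_names),
            class = "node_attributes")
}

#' Read node attributes from TSV (`node_id  x  y  z ...`)
#' @param path file path.
#' @return a [node_attributes()] table.
#' @export
read_attributes <- function(path) {
  df <- read.table(path, header = FALSE, colClasses = "character")
  vals <- apply(df[, -1, drop = FALSE], 2, as.numeric)
  vals <- matrix(vals, nrow = nrow(df))
  node_attributes(vals, df[[1]])
}

#' Write node attributes as TSV
#' @param attributes a [node_attributes()] table.
#' @param path output path.
#' @export
write_attributes <- function(attributes, path) {
  df <- data.frame(id = attributes$node_ids,
                   format(attributes$values, digits = 17, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
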