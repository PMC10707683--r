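#' Community partition
#'
#' Assignment of every node to exactly one integer community label.
#' Stored as a named integer vector (names = node ids, values = labels).
#'
#' @param labels integer-valued vector of community labels, named by node
#'   id (or unnamed with `node_ids` supplied).
#' @param node_ids optional node ids when `labels` is unnamed.
#' @return object of class `partition`.
#' @examples
#' p <- partition(c(a = 1, b = 1, c = 2))
#' n_communities(p)
#' @export
partition <- function(labels, node_ids = NULL) {
  if (length(labels) == 0) stop("empty partition")
  if (!is.null(node_ids)) names(labels) <- as.character(node_ids)
  if (is.null(names(labels))) names(labels) <- as.character(seq_along(labels))
  lab <- as.integer(round(as.numeric(labels)))
  if (any(is.na(lab))) stop("community labels must be integers")
  names(lab) <- names(labels)
  if (anyDuplicated(names(lab))) stop("duplicate node ids in partition")
  structure(lab, class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities\n",
              length(x), n_communities(x)))
  invisible(x)
}

#' @rdname partition
#' @param x object to test.
#' @export
is_partition <- function(x) inherits(x, "partition")

#' Number of distinct communities in a partition
#' @param p a [partition()].
#' @export
n_communities <- function(p) length(unique(as.integer(p)))

#' Community sizes of a partition
#' @param p a [partition()].
#' @return named integer vector (names = community labels, sorted).
#' @export
community_sizes <- function(p) {
  tab <- table(as.integer(p))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(as.integer(names(out)))]
}

#' Ordered collection of partitions over one node set
#'
#' The "partition pool" structure: every member must cover the identical
#' node set; members are reordered to the first member's node order.
#'
#' @param partitions list of [partition()] objects.
#' @return object of class `partition_ensemble`.
#' @export
partition_ensemble <- function(partitions) {
  if (!length(partitions)) stop("empty ensemble")
  partitions <- lapply(partitions, function(p) {
    if (!is_partition(p)) p <- partition(p)
    p
  })
  ref <- names(partitions[[1]])
  partitions <- lapply(partitions, function(p) {
    if (!setequal(names(p), ref))
      stop("ensemble members must cover the identical node set")
    partition(as.integer(p)[match(ref, names(p))], ref)
  })
  structure(list(partitions = partitions, size = length(partitions)),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> %d partitions over %d nodes\n",
              x$size, length(x$partitions[[1]])))
  invisible(x)
}

#' Label matrix of an ensemble (nodes x partitions)
#' @param ensemble a [partition_ensemble()].
#' @keywords internal
ensemble_label_matrix <- function(ensemble) {
  do.call(cbind, lapply(ensemble$partitions, as.integer))
}

#' Write a partition as TSV (`node_id  community_label`)
#' @param partition a [partition()].
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  if (!is_partition(partition)) stop("not a partition")
  df <- data.frame(id = names(partition), label = as.integer(partition))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a partition from TSV (`node_id  community_label`)
#' @param path file path.
#' @export
read_partition <- function(path) {
  df <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("partition file needs two columns")
  partition(as.integer(df[[2]]), df[[1]])
}
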