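#' ROI time-series container
#'
#' `R x T` matrix of region-of-interest time courses (rows = ROIs).
#'
#' @param values numeric `R x T` matrix.
#' @param roi_ids character ROI labels (length `R`).
#' @export
roi_timeseries <- function(values, roi_ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 3) stop("need at least 3 time points")
  if (any(!is.finite(values))) stop("non-finite time-series values")
  if (is.null(roi_ids)) roi_ids <- rownames(values)
  if (is.null(roi_ids)) roi_ids <- as.character(seq_len(nrow(values)))
  rownames(values) <- as.character(roi_ids)
  structure(list(values = values, roi_ids = as.character(roi_ids)),
            class = "roi_timeseries")
}

#' Read ROI time series from CSV/TSV (first column = ROI id)
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
read_roi_timeseries <- function(path, sep = "\t") {
  df <- read.table(path, header = FALSE, sep = sep,
                   colClasses = "character")
  vals <- apply(df[, -1, drop = FALSE], 2, as.numeric)
  roi_timeseries(matrix(vals, nrow = nrow(df)), df[[1]])
}

#' Pearson correlation matrix of ROI time courses
#'
#' @param ts a [roi_timeseries()]; every ROI must have nonzero variance.
#' @return symmetric `R x R` correlation matrix, diagonal 1.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- apply(ts$values, 1, sd)
  if (any(v == 0)) stop("zero-variance ROI(s): ",
                        paste(head(ts$roi_ids[v == 0], 5), collapse = ", "))
  r <- cor(t(ts$values))
  dimnames(r) <- list(ts$roi_ids, ts$roi_ids)
  r
}

#' Fisher r-to-z transform (and inverse)
#'
#' `z = atanh(r)` applied off-diagonal (the unit diagonal is left at 0 in
#' z space and restored to 1 by the inverse); `inverse_fisher(fisher_z(r))`
#' reproduces `r` to machine precision.
#'
#' @param r correlation matrix with `|r| < 1` off-diagonal.
#' @return transformed matrix.
#' @export
fisher_z <- function(r) {
  r <- as.matrix(r)
  off <- r; diag(off) <- 0
  if (any(abs(off) >= 1)) stop("|r| = 1 off-diagonal: z undefined")
  z <- atanh(off)
  z
}

#' @rdname fisher_z
#' @param z a z-transformed matrix.
#' @export
inverse_fisher <- function(z) {
  r <- tanh(as.matrix(z))
  diag(r) <- 1
  r
}

#' Resampled group-average correlation matrices
#'
#' For each of `n_resamples` draws, averages the z-matrices of a random
#' `subset_size`-subject subset and back-transforms (inverse Fisher),
#' mirroring the leave-some-out group-network construction.
#'
#' @param z_matrices list of subject z-matrices (same dimensions).
#' @param subset_size subjects per resample (default 90).
#' @param n_resamples number of group matrices (default 100).
#' @param seed integer seed.
#' @return list of `n_resamples` correlation matrices.
#' @export
group_average <- function(z_matrices, subset_size = 90L, n_resamples = 100L,
                          seed = 1L) {
  if (!length(z_matrices)) stop("empty matrix list")
  ns <- length(z_matrices)
  stopifnot(subset_size >= 1, subset_size <= ns)
  picks <- with_seed(seed, lapply(seq_len(n_resamples), function(i)
    sample.int(ns, subset_size, replace = FALSE)))
  lapply(picks, function(ix)
    inverse_fisher(Reduce(`+`, z_matrices[ix]) / subset_size))
}

#' Density-threshold a correlation matrix into a weighted network
#'
#' Negative entries are zeroed first (ambiguous physiological meaning),
#' then exactly `floor(R (R - 1) / 2 * density)` largest positive
#' off-diagonal weights are retained (fewer if the matrix has fewer
#' positive entries); surviving edges keep their correlation weights. Ties
#' at the quota boundary break by lexicographic `(i, j)` order. Isolated
#' nodes remain in the network as singletons.
#'
#' @param matrix symmetric `R x R` correlation-like matrix.
#' @param density fraction `S` of all node pairs to retain, in `(0, 1]`.
#' @return a [weighted_network()].
#' @export
threshold_to_density <- function(matrix, density) {
  stopifnot(density > 0, density <= 1)
  m <- as.matrix(matrix)
  R <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(R))
  quota <- floor(R * (R - 1) / 2 * density)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(quota, length(ord)))]
  A <- (m * 0)
  if (length(keep)) {
    A[ut[keep, , drop = FALSE]] <- w[keep]
    A[ut[keep, c(2, 1), drop = FALSE]] <- w[keep]
  }
  diag(A) <- 0
  weighted_network(A, ids)
}

#' Simulate block-structured subject ROI time series
#'
#' Latent-signal model for pipeline tests without imaging data: every ROI
#' in block `b` follows \eqn{x(t) = \sqrt{\rho}\, g_b(t) +
#' \sqrt{1 - \rho}\, e(t)} with standard normal latent block signals
#' `g_b` and i.i.d. noise `e`, so the expected within-block correlation is
#' `rho` and between-block correlation is 0.
#'
#' @param membership a [partition()] giving each ROI's block.
#' @param n_time time points per subject (default 200).
#' @param n_subjects number of subjects (default 1).
#' @param block_cor target within-block correlation `rho` (default 0.6).
#' @param seed integer seed.
#' @return list of [roi_timeseries()] of length `n_subjects`.
#' @export
simulate_roi_timeseries <- function(membership, n_time = 200L,
                                    n_subjects = 1L, block_cor = 0.6,
                                    seed = 1L) {
  if (!is_partition(membership)) membership <- partition(membership)
  stopifnot(block_cor >= 0, block_cor < 1)
  lab <- as.integer(membership)
  blocks <- sort(unique(lab))
  Rn <- length(lab)
  with_seed(seed, lapply(seq_len(n_subjects), function(su) {
    G <- matrix(rnorm(length(blocks) * n_time), length(blocks), n_time)
    E <- matrix(rnorm(Rn * n_time), Rn, n_time)
    X <- sqrt(block_cor) * G[match(lab, blocks), , drop = FALSE] +
      sqrt(1 - block_cor) * E
    roi_timeseries(X, names(membership))
  }))
}
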