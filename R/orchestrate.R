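#' Run one detection method on an edge-list file, with a manifest
#'
#' Front-end used by the command-line interface: reads the network, runs
#' the requested method, writes the partition (TSV) and a JSON manifest
#' recording input checksums, parameters, the root seed and the package
#' version. Writes are atomic (temp file + rename) and a rerun with the
#' same inputs and seed is byte-identical.
#'
#' @param input path to an edge-list TSV.
#' @param method one of `"mm"`, `"wmm"`, `"robust_mm"`, `"two_step"`.
#' @param output_dir directory for outputs (created if missing).
#' @param attributes optional path to a node-attribute TSV (required for
#'   `"two_step"`).
#' @param params named list of method parameters overriding the defaults
#'   (`gamma`, `pool_size`, `n_selected`, `n_selections`, `n_null`,
#'   `alpha`, `n_perm`, `min_subdivide_size`).
#' @param seed root seed.
#' @param name basename for the output files (default derived from the
#'   method).
#' @return invisibly, a list with `partition_file`, `manifest_file` and
#'   the partition object.
#' @export
run_detection <- function(input, method = c("mm", "wmm", "robust_mm",
                                            "two_step"),
                          output_dir = ".", attributes = NULL,
                          params = list(), seed = 1L, name = NULL) {
  method <- match.arg(method)
  if (method == "two_step" && is.null(attributes))
    stop("two_step requires an attributes file")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  net <- read_edge_list(input)
  defaults <- list(gamma = 1, pool_size = 100L, n_selected = 50L,
                   n_selections = 50L, n_null = 1000L, alpha = 0.05,
                   n_perm = 10000L, min_subdivide_size = 6L)
  p <- modifyList(defaults, params)

  attrs <- if (!is.null(attributes)) read_attributes(attributes)
  result <- switch(method,
    mm = louvain_optimize(net, gamma = p$gamma, seed = seed),
    wmm = wmm(net, p$pool_size, p$n_selected, p$n_selections, p$gamma,
              seed = seed),
    robust_mm = robust_mm(net, p$pool_size, p$n_null, p$alpha, p$gamma,
                          seed = seed),
    two_step = two_step_wmm(net, attrs, p$n_perm, p$alpha,
                            p$min_subdivide_size, p$pool_size,
                            p$n_selected, p$n_selections, p$gamma,
                            seed = seed))

  if (is.null(name)) name <- method
  part_file <- file.path(output_dir, paste0(name, "_partition.tsv"))
  if (method == "two_step") {
    atomic_write(part_file, function(tmp)
      write_hierarchical_partition(result, tmp))
    part <- result$level2
  } else {
    atomic_write(part_file, function(tmp) write_partition(result, tmp))
    part <- result
  }

  manifest <- list(
    method = method,
    input = basename(input),
    input_md5 = unname(tools::md5sum(input)),
    attributes_md5 = if (!is.null(attributes))
      unname(tools::md5sum(attributes)) else NULL,
    parameters = p[intersect(names(p), switch(method,
      mm = "gamma",
      wmm = c("gamma", "pool_size", "n_selected", "n_selections"),
      robust_mm = c("gamma", "pool_size", "n_null", "alpha"),
      two_step = c("gamma", "pool_size", "n_selected", "n_selections",
                   "n_perm", "alpha", "min_subdivide_size")))],
    root_seed = as.integer(seed),
    derived_seed_scheme = "spawn_seeds(root, n): sample.int(2^31-2) under set.seed(root)",
    n_nodes = n_nodes(net),
    n_communities = n_communities(part),
    package = "wmmnet",
    version = as.character(utils::packageVersion("wmmnet")))
  manifest_file <- file.path(output_dir, paste0(name, "_manifest.json"))
  atomic_write(manifest_file, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null"))
  invisible(list(partition_file = part_file, manifest_file = manifest_file,
                 result = result))
}

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Paired method-comparison study on generated benchmarks
#'
#' Reproduces the simulation study's aggregation scheme at configurable
#' scale: for every benchmark spec, generate the network, run each method
#' `runs_per_network` times (independent child seeds; the same networks
#' serve all methods, giving a paired design), score every run's NMI
#' against the planted partition, and summarize per network by the mean
#' NMI and the mean average node entropy of the run ensemble.
#'
#' @param specs list of [benchmark_spec()]s (attributed specs allowed;
#'   required for `"two_step"`).
#' @param methods subset of `"mm"`, `"wmm"`, `"robust_mm"`, `"two_step"`.
#' @param runs_per_network repeated runs per network per method.
#' @param pool_size,n_selected,n_selections,gamma consensus configuration
#'   (see [wmm()]); also reused inside `robust_mm` and `two_step`.
#' @param n_perm,alpha two-step permutation-test settings.
#' @param seed root seed.
#' @return list with `runs` (one row per run: network, method, run, nmi)
#'   and `networks` (one row per network x method: mean NMI, mean average
#'   node entropy, realized `mu`/size metadata).
#' @export
run_comparison_study <- function(specs, methods = c("mm", "wmm"),
                                 runs_per_network = 20L, pool_size = 100L,
                                 n_selected = 50L, n_selections = 50L,
                                 gamma = 1, n_perm = 2000L, alpha = 0.05,
                                 seed = 1L) {
  stopifnot(length(specs) >= 1)
  methods <- match.arg(methods, c("mm", "wmm", "robust_mm", "two_step"),
                       several.ok = TRUE)
  net_seeds <- spawn_seeds(seed, length(specs))
  runs <- list()
  nets <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    attributed <- inherits(spec, "attributed_benchmark_spec")
    if ("two_step" %in% methods && !attributed)
      stop("two_step requested but spec ", si, " has no attributes")
    gen <- if (attributed) generate_attributed_benchmark(spec) else
      generate_weighted_benchmark(spec)
    truth <- gen$partition
    run_seeds <- spawn_seeds(net_seeds[si],
                             length(methods) * runs_per_network)
    k <- 0L
    for (m in methods) {
      parts <- vector("list", runs_per_network)
      for (r in seq_len(runs_per_network)) {
        k <- k + 1L
        parts[[r]] <- switch(m,
          mm = louvain_optimize(gen$network, gamma = gamma,
                                seed = run_seeds[k]),
          wmm = wmm(gen$network, pool_size, n_selected, n_selections,
                    gamma, seed = run_seeds[k]),
          robust_mm = robust_mm(gen$network, pool_size, gamma = gamma,
                                seed = run_seeds[k]),
          two_step = two_step_wmm(gen$network, gen$attributes,
                                  n_perm = n_perm, alpha = alpha,
                                  pool_size = pool_size,
                                  n_selected = n_selected,
                                  n_selections = n_selections,
                                  gamma = gamma,
                                  seed = run_seeds[k])$level2)
        runs[[length(runs) + 1L]] <- data.frame(
          network = si, method = m, run = r,
          nmi = nmi(parts[[r]], truth))
      }
      ens <- partition_ensemble(parts)
      nets[[length(nets) + 1L]] <- data.frame(
        network = si, method = m,
        n_nodes = spec$n_nodes, mu = spec$mu_t,
        mean_nmi = mean(vapply(parts, nmi, numeric(1), y = truth)),
        mean_entropy = if (runs_per_network >= 2)
          mean_average_node_entropy(ens) else NA_real_)
    }
  }
  list(runs = do.call(rbind, runs), networks = do.call(rbind, nets))
}
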