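# wmmnet

Stable and hierarchical community detection for undirected weighted
networks, built around **consensus-weighted modularity maximization**.

## Who this is for

Modularity maximization (MM) with a Louvain-style optimizer is the
workhorse of community detection in systems neuroscience and network
biology, but it is unstable: the modularity landscape has many
near-degenerate local maxima, so repeated runs on the same network —
e.g. a group-level resting-state functional connectivity matrix — return
different parcellations. And a single MM pass is flat: it cannot expose
the nested community structure brain networks are believed to have.
`wmmnet` is for anyone who needs *reproducible* partitions of weighted
networks (connectomes, correlation networks, any symmetric non-negative
similarity structure) and, optionally, a statistically gated second
level of resolution.

## The methods

All methods optimize the (unnormalized) modularity with the
Newman–Girvan null model and resolution parameter γ,

    Q = Σ_ij [ A_ij − γ·k_i·k_j / 2U ] · δ(σ_i, σ_j),

via a seeded, deterministic Louvain kernel written in C++.

* **WMM** (`wmm()`): build a pool of L = 100 MM partitions; K = 50 times,
  average the association (co-assignment) matrices of M = 50 randomly
  selected pool members into a weight matrix W_i and rerun MM on the
  Hadamard product A ⊗ W_i; average those K partitions' association
  matrices into the final weight matrix W′; run MM once on A ⊗ W′.
  Filtering the adjacency matrix by empirical co-assignment probability
  sharpens community structure and suppresses the optimizer's run-to-run
  variability.
* **Robust MM** (`robust_mm()`): the consensus baseline — MM on the
  pool's mean association matrix thresholded against a size-preserving
  label-permutation null.
* **Two-step WMM** (`two_step_wmm()`): WMM, then WMM again inside every
  sufficiently large community; a subdivision is kept only when it
  lowers the community's mean spatial distance d = (1/N²)·ΣΣ D_ij on the
  node attributes (e.g. 3-D region coordinates) below the α = 0.05
  quantile of a size-preserving permutation null (T = 10,000 shuffles).
* **Metrics**: normalized mutual information (`nmi()`) for accuracy and
  mean **average node entropy** (`mean_average_node_entropy()`) — the
  node-wise Shannon entropy of reference-matched labels across repeated
  runs — for stability (lower = more stable).
* **Generators**: weighted planted-partition benchmarks with power-law
  degrees/community sizes and degree+strength mixing parameters
  (`generate_weighted_benchmark()`), attributed unweighted analogues
  (`generate_attributed_benchmark()`), a nested-block hierarchy fixture
  (`generate_hierarchical_fixture()`), and the full simulation grid
  (`experiment_grid()`).
* **fMRI stage** (`correlation_matrix()`, `fisher_z()`,
  `group_average()`, `threshold_to_density()`): ROI time series →
  Pearson → Fisher z → resampled group averages → negative-edge zeroing
  and density thresholding at floor(R(R−1)/2·S) edges.

See `vignettes/consensus-modularity.Rmd` for the full methods account,
parameter rationale and limitations.

## Worked example

```r
library(wmmnet)

spec  <- benchmark_spec(n_nodes = 300, mean_degree = 15, max_degree = 75,
                        mu_t = 0.5, seed = 42)
bench <- generate_weighted_benchmark(spec)
bench$network
#> <weighted_network> 300 nodes, 2225 edges, total weight 2U = 20884

p_mm  <- louvain_optimize(bench$network, seed = 1)
p_wmm <- wmm(bench$network, seed = 1)
nmi(p_mm,  bench$partition)   # 0.703
nmi(p_wmm, bench$partition)   # 0.777

runs_mm  <- lapply(1:10, function(r) louvain_optimize(bench$network, seed = r))
runs_wmm <- lapply(1:10, function(r) wmm(bench$network, seed = r))
mean_average_node_entropy(partition_ensemble(runs_mm))   # 0.26 bits
mean_average_node_entropy(partition_ensemble(runs_wmm))  # 0 bits
```

At mixing μ = 0.5 (half of every node's degree and strength crosses
community boundaries) plain MM recovers the planted partition with
NMI 0.70 and wobbles across seeds (0.26 bits of label entropy per node);
WMM is both more accurate (0.78) and, here, perfectly stable (0 bits).

Hierarchy, with node coordinates as attributes:

```r
fx <- generate_hierarchical_fixture(n_super = 2, n_sub_per_super = 2,
                                    sub_size = 25, spatial_sep = 5,
                                    sigma = 0.5, seed = 4)
h <- two_step_wmm(fx$network, fx$attributes, n_perm = 2000, seed = 1)
h
#> <hierarchical_partition> level 1: 2 communities; level 2: 4 communities
#> (2 subdivisions accepted)
nmi(h$level1, fx$level1)   # 1 — super-blocks recovered
nmi(h$level2, fx$level2)   # 1 — all four spatial sub-blocks recovered
h$test_results[[1]][c("d_before", "d_after", "null_quantile")]
#> d_before 3.11, d_after 1.07, null quantile 2.93
```

The first community's mean spatial distance drops from 3.11 to 1.07 on
subdivision, far below the 5% null quantile (2.93), so the split is
accepted.

## Command line

```sh
Rscript inst/cli/wmmnet.R detect wmm --input edges.tsv --pool 100 \
        --m 50 --k 50 --gamma 1.0 --seed 7 --out out/
Rscript inst/cli/wmmnet.R simulate benchmark --n 300 --mean-degree 15 \
        --maxk 75 --mu 0.4 --reps 20 --seed 7 --out nets/
Rscript inst/cli/wmmnet.R evaluate nmi --a part1.tsv --b part2.tsv
```

Every detection run writes a JSON manifest (input checksums, parameters,
root seed); reruns with the same seed are byte-identical.

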