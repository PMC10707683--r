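---
title: "Consensus-weighted modularity maximization: models, choices, caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-weighted modularity maximization: models, choices, caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Modularity maximization (MM) partitions a weighted undirected network by
maximizing

$$Q = \sum_{ij}\left[A_{ij} - \gamma\,\frac{k_i k_j}{2U}\right]
      \delta(\sigma_i,\sigma_j),$$

where $A$ is the adjacency matrix, $k_i = \sum_j A_{ij}$ the node
strength, $2U = \sum_{ij} A_{ij}$, $\gamma$ a resolution parameter, and
$\delta$ the Kronecker delta over community labels. Two well-known
practical defects motivate this package:

* **Instability.** The modularity landscape has exponentially many
  near-optimal local maxima; a Louvain-style greedy optimizer started
  from different random node orders returns different partitions. For
  applications such as group-level brain-network parcellation this
  run-to-run variability is a serious problem.
* **Flat output.** MM returns a single partition scale and cannot by
  itself expose the nested community structure that brain networks are
  widely believed to have.

`wmmnet` addresses the first problem with **weighted modularity
maximization (WMM)** — two rounds of consensus filtering of the adjacency
matrix — and the second with **two-step WMM**, which subdivides a
community only when an attribute-based permutation test supports the
split. A permutation-thresholded consensus baseline (**robust MM**) is
included for comparison.

Note on scale: $Q$ is implemented on the *unnormalized* scale shown above
(no $1/2U$ prefactor). The optimizing partition is identical either way;
`modularity_q(..., normalized = TRUE)` divides by $2U$ for display and for
comparisons with other software.

## WMM

With one root seed, `wmm()` performs:

1. a pool of $L$ independent Louvain runs on $A$ (default $L = 100$);
2. $K$ random subsets of $M$ pool members (defaults $M = K = 50$), each
   averaged into a co-assignment weight matrix $W_i$ with
   $W_{i,jk} \in [0,1]$;
3. one Louvain run on each filtered matrix $A \otimes W_i$ (Hadamard
   product), with the null model recomputed from the filtered strengths;
4. the final weight matrix $W'$ as the mean association matrix of those
   $K$ second-round partitions;
5. a final Louvain run on $A \otimes W'$.

The filtering sharpens the contrast between edges that are consistently
intra-community across runs and edges that are not; the second round
exists because the first-round weight matrices inherit some of the pool's
instability. Defaults ($L = 100$, $M = K = 50$, $\gamma = 1$) are the
configuration used throughout the simulation study this package
replicates; they are deliberately not adaptive.

Subset selections are drawn *without replacement* within a selection and
independently across the $K$ selections. The diagonal of every weight
matrix is fixed at 1; it is irrelevant because $A_{ii} = 0$. Nodes
isolated by filtering become singleton communities in subsequent runs.

## The Louvain kernel

The optimizer (C++, `src/louvain.cpp`) is a standard two-phase local-move
/ aggregation scheme with these pinned-down choices:

* node visiting order is re-shuffled each sweep from a private,
  seed-initialized RNG — runs are exactly reproducible and platform
  independent (explicit Fisher–Yates, no `std::shuffle`);
* a move is accepted only if its gain exceeds `1e-12` on the unnormalized
  $Q$ scale; on ties the current community wins, otherwise the lowest
  candidate community label — determinism again;
* aggregation repeats until no merge occurs, with `max_passes` (default
  50) as a guard;
* an edgeless network returns all-singletons rather than an error;
  isolated nodes always end as singletons.

## Robust MM

The baseline stabilization thresholds the pool's mean association matrix
$\bar W$ against a null in which every pool partition's labels are
randomly reassigned to nodes with community sizes fixed. For a fixed node
pair under such a permutation, co-assignment in pool member $m$ is a
Bernoulli event with probability
$p_m = \sum_c n_c (n_c - 1) / (N (N - 1))$, so the null association entry
is distributed as the mean of $L$ independent Bernoullis. The
implementation samples this **exact marginal law** `n_null` times
(default 1000) instead of materializing permuted $N \times N$ matrices —
identical distribution, orders of magnitude cheaper. Entries of $\bar W$
must *strictly* exceed the $(1-\alpha)$ null quantile to survive: with a
`>=` rule a degenerate pool of identical one-community partitions would
keep a saturated all-ones matrix, with the strict rule it empties and the
final partition falls back to singletons. That corner case is documented
behavior, not an error.

## Two-step WMM

Step one is `wmm()` on the full network. Step two revisits every
first-step community $C$ with at least `min_subdivide_size` nodes
(default 6, mirroring the practice of leaving communities of five or
fewer regions undivided in real parcellation work), runs WMM on the
induced subnetwork, and tests the proposed split against the node
attributes — for brain networks, 3-D region coordinates.

The spatial distance of a community with $N_c$ nodes is the *literal*
grand mean

$$d = \frac{1}{N_c^2} \sum_i \sum_j D_{ij},$$

zero diagonal included (a singleton has $d = 0$). The off-diagonal mean
$1/(N_c(N_c-1))$ would be the unbiased choice, but the permutation null
uses the same formula, so the convention cancels inside the test; the
printed formula is followed. The post-subdivision distance is the
**unweighted** mean of $d$ over sub-communities (not size-weighted).

The null shuffles node-to-subcommunity assignments $T$ times (default
10,000) with sizes and count fixed, entirely within the community —
outside nodes never enter. With null distances sorted ascending, the
split is accepted iff $d_\text{after} < d_\text{before}$ *and*
$d_\text{after}$ is below the $\lceil T\alpha\rceil$-th smallest null
value. `n_perm * alpha < 1` is an error, not a silent degenerate test.
A community whose second-step WMM finds no split (one community) is
retained untested — there is nothing to compare. Retained communities
keep their level-1 labels; accepted subdivisions get fresh labels above
the level-1 maximum, so level 2 always refines level 1. Recursion stops
at two levels by definition of the method; deeper nesting is out of
scope. The full WMM configuration is reused on each subgraph (exposed as
arguments, since the appropriate pool size for a 50-node subgraph is a
judgment call).

## Accuracy and stability metrics

**NMI** is $2\,\mathrm{MI}(X,Y) / (H(X){+}H(Y))$ from the contingency
table of two partitions. If both partitions are the trivial
one-community partition the formula is $0/0$; they are then identical and
the value is defined as 1.

**Average node entropy** measures stability of an ensemble of runs:
members are label-matched against a reference member, each node's
base-2 Shannon entropy of matched labels across the ensemble is computed,
and the node mean is taken. The reported index,
`mean_average_node_entropy()`, averages over every choice of reference.
Entropy is unnormalized and labeled in bits; any fixed base would only
rescale comparisons. Label matching is greedy by descending overlap size
with ties to the smallest reference label (then smallest partition
label); unmatched communities get fresh labels. Greedy matching is
deterministic and cheap; an exhaustive optimal-assignment variant is
available via `match_labels(..., method = "optimal")` for sensitivity
checks on small community counts.

## Synthetic benchmarks: what they emulate and what they do not

`generate_weighted_benchmark()` emulates the statistical structure of the
classic weighted planted-partition (LFR-style) design: truncated
power-law degrees (exponent $\tau_1$, lower cutoff solved numerically so
the continuous mean matches $\langle k\rangle$), power-law community
sizes (exponent $\tau_2$) adjusted minimally to sum to $N$ with every
community large enough for its members' internal degrees, strengths
$s_i = k_i^\beta$, and mixing parameters $\mu_t$ (degree) and $\mu_w$
(strength) giving the expected inter-community fractions. Wiring is a
degree-corrected planted-partition (Chung–Lu) scheme with a dozen
proportional-fitting rounds to cancel the self-exclusion and clamping
biases — measured realized moments: mean degree within ~4% of target and
mixing within ~0.01 at $N \ge 100$. It is *not* the original rewiring
algorithm: exact degree sequences are not enforced edge-for-edge, and
tiny networks ($N = 50$) show larger relative deviations. Strength
budgets are spread equally over a node's incident edges of each kind and
symmetrized by endpoint averaging.

`generate_attributed_benchmark()` produces the unweighted analogue with
`n_attributes` (default 3) Gaussian attributes per node around
community centers placed on a unit-spaced integer grid, so the attribute
standard deviation $\sigma$ directly controls cluster overlap; the
original attributed-benchmark package's center placement is unspecified,
and this deterministic grid is the package's own documented choice.

`generate_hierarchical_fixture()` is a nested stochastic block model
($p_\text{in-sub} > p_\text{in-super} > p_\text{out}$) with spatially
separated sub-block centers; it exists to give the two-step gate a ground
truth with *known* hierarchy, something the flat benchmarks cannot.

A green directional test on these generators therefore establishes that
the implemented methods rank as published *on networks with this
statistical structure*; it does not certify behavior on real rs-fMRI
correlation networks, whose noise is neither power-law-degree nor
block-Gaussian.

## Group correlation networks

The rs-fMRI construction stage operates on ROI × time matrices: Pearson
correlations, Fisher $z$, subset averaging ($90$ of $100$ subjects,
$100$ resamples by default), inverse Fisher, negative-edge zeroing, then
density thresholding that keeps exactly
$\lfloor R(R-1)/2 \cdot S\rfloor$ largest positive off-diagonal weights
(fewer when fewer positives exist — a documented shortfall, not an
error). Negatives are zeroed *before* ranking so the retained set is
all-positive regardless of quota; ties at the quota boundary break by
lexicographic $(i,j)$ order; `floor` rather than rounding is used for the
quota. Isolated nodes — the known low-density pathology — stay in the
network as singletons. A latent block-signal subject simulator
(`simulate_roi_timeseries()`) makes the whole pipeline testable without
imaging data; it reproduces block correlation structure but none of the
temporal autocorrelation, motion artifacts, or spatial smoothness of real
acquisitions.

## Seeds and reproducibility

Every stochastic stage draws its seed through `spawn_seeds(root, n)`
(child seeds sampled uniformly from $1..2^{31}-2$ under a temporarily
seeded RNG; the caller's RNG state is restored). A pipeline run is a pure
function of its root seed; `run_detection()` records root seed, scheme,
parameters and input checksums in a JSON manifest, and reruns are
byte-identical.

## Known limitations

* Dense-matrix internals: fine to a few thousand nodes (the target
  regime is $N \le 1000$ benchmarks and a 333-ROI atlas), not for
  $10^5$-node graphs.
* Negative edge weights are rejected rather than modeled; signed
  modularity is out of scope.
* Two hierarchy levels only.
* The robust-MM null is the label-permutation null; other nulls
  (e.g. rewiring nulls) would shift the threshold and are not provided.
* Benchmarks emulate, not reproduce, the external generator binaries;
  quantitative agreement with published *curves* is therefore assessed
  directionally, not point-by-point.
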