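// Louvain-style greedy optimizer of the unnormalized modularity
//   Q = sum_ij [A_ij - gamma * k_i k_j / 2U] delta(s_i, s_j)
// plus small numeric kernels used by the consensus and hierarchy stages.
//
// Determinism contract: all randomness comes from a user-supplied integer
// seed driving a private mt19937; shuffling uses an explicit Fisher-Yates
// with rejection sampling so results do not depend on the C++ standard
// library's std::shuffle implementation.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline uint32_t rand_below(std::mt19937 &rng, uint32_t n) {
  // uniform on 0..n-1 without modulo bias
  uint32_t lim = UINT32_MAX - (UINT32_MAX % n);
  uint32_t x;
  do {
    x = rng();
  } while (x >= lim);
  return x % n;
}

static void shuffle_ints(std::vector<int> &v, std::mt19937 &rng) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int j = static_cast<int>(rand_below(rng, static_cast<uint32_t>(i + 1)));
    std::swap(v[i], v[j]);
  }
}

// One level of local moves on a dense (possibly self-looped, aggregated)
// matrix. Returns membership 0..nc-1 relabeled by first occurrence.
// Tie rule: keep the current community on a tied gain, otherwise the
// lowest-labeled strictly better candidate wins.
static std::vector<int> local_moves(const std::vector<double> &A, int n,
                                    double gamma, double twoU,
                                    std::mt19937 &rng, double tol,
                                    int max_sweeps) {
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double *row = &A[static_cast<size_t>(i) * n];
    for (int j = 0; j < n; ++j) s += row[j];
    k[i] = s;
  }
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;
  std::vector<double> tot(k);  // strength sum per community
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> cw(n, 0.0);  // edge weight from node i to community c
  std::vector<int> touched;
  touched.reserve(64);

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    shuffle_ints(order, rng);
    int n_moves = 0;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      const double *row = &A[static_cast<size_t>(i) * n];
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double w = row[j];
        if (w != 0.0) {
          int c = comm[j];
          if (cw[c] == 0.0) touched.push_back(c);
          cw[c] += w;
        }
      }
      int ci = comm[i];
      tot[ci] -= k[i];
      bool cur_in = false;
      for (size_t t = 0; t < touched.size(); ++t)
        if (touched[t] == ci) { cur_in = true; break; }
      if (!cur_in) touched.push_back(ci);
      std::sort(touched.begin(), touched.end());

      double best_gain = cw[ci] - gamma * k[i] * tot[ci] / twoU;
      int best = ci;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == ci) continue;
        double g = cw[c] - gamma * k[i] * tot[c] / twoU;
        if (g > best_gain + tol) {
          best_gain = g;
          best = c;
        }
      }
      tot[best] += k[i];
      if (best != ci) {
        comm[i] = best;
        ++n_moves;
      }
      for (size_t t = 0; t < touched.size(); ++t) cw[touched[t]] = 0.0;
      if (cw[ci] != 0.0) cw[ci] = 0.0;  // ci may not be in touched originally
    }
    if (n_moves == 0) break;
  }

  // relabel by first occurrence
  std::vector<int> map(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return comm;
}

static std::vector<double> aggregate(const std::vector<double> &A, int n,
                                     const std::vector<int> &comm, int nc) {
  std::vector<double> B(static_cast<size_t>(nc) * nc, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *row = &A[static_cast<size_t>(i) * n];
    double *brow = &B[static_cast<size_t>(comm[i]) * nc];
    for (int j = 0; j < n; ++j) brow[comm[j]] += row[j];
  }
  return B;
}

// [[Rcpp::export]]
IntegerVector cpp_louvain(NumericMatrix Ain, double gamma, int seed,
                          int max_passes, double tol) {
  int n = Ain.nrow();
  IntegerVector out(n);
  std::vector<double> A(Ain.begin(), Ain.end());  // symmetric: layout moot
  double twoU = 0.0;
  for (size_t t = 0; t < A.size(); ++t) twoU += A[t];
  if (twoU <= 0.0) {
    for (int i = 0; i < n; ++i) out[i] = i + 1;
    return out;
  }
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<int> final_comm(n);
  for (int i = 0; i < n; ++i) final_comm[i] = i;
  std::vector<double> cur(A);
  int m = n;
  for (int pass = 0; pass < max_passes; ++pass) {
    std::vector<int> comm = local_moves(cur, m, gamma, twoU, rng, tol, 1000);
    int nc = 1 + *std::max_element(comm.begin(), comm.end());
    for (int i = 0; i < n; ++i) final_comm[i] = comm[final_comm[i]];
    if (nc == m) break;  // no merge: converged
    cur = aggregate(cur, m, comm, nc);
    m = nc;
  }

  std::vector<int> map(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int c = final_comm[i];
    if (map[c] < 0) map[c] = next++;
    out[i] = map[c] + 1;
  }
  return out;
}

// Null distribution for the two-step subdivision test: T size-preserving
// random reassignments of nodes to sub-communities; each yields the mean
// over groups of (sum of D within group, diagonal included) / size^2.
// [[Rcpp::export]]
NumericVector cpp_perm_null(NumericMatrix D, IntegerVector sizes, int T,
                            int seed) {
  int n = D.nrow();
  int k = sizes.size();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector out(T);
  for (int t = 0; t < T; ++t) {
    shuffle_ints(idx, rng);
    double acc = 0.0;
    int pos = 0;
    for (int g = 0; g < k; ++g) {
      int s = sizes[g];
      double ssum = 0.0;
      for (int a = 0; a < s; ++a) {
        int ia = idx[pos + a];
        for (int b = 0; b < s; ++b) ssum += D(ia, idx[pos + b]);
      }
      acc += ssum / (static_cast<double>(s) * s);
      pos += s;
    }
    out[t] = acc / k;
  }
  return out;
}

// Stack binary co-assignment (association) matrices of an ensemble as the
// columns of an N^2 x L matrix, so selection averages reduce to one BLAS
// product in R. labels: N x L integer matrix of community labels.
// [[Rcpp::export]]
NumericMatrix cpp_assoc_flat(IntegerMatrix labels) {
  int n = labels.nrow();
  int L = labels.ncol();
  NumericMatrix out(n * n, L);
  for (int l = 0; l < L; ++l) {
    double *col = &out(0, l);
    const int *lab = &labels(0, l);
    for (int j = 0; j < n; ++j) {
      int lj = lab[j];
      double *c2 = col + static_cast<size_t>(j) * n;
      for (int i = 0; i < n; ++i) c2[i] = (lab[i] == lj) ? 1.0 : 0.0;
    }
  }
  return out;
}
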