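#include <Rcpp.h>
#include "rng.h"
#include <vector>
using namespace Rcpp;

// Gibbs sampling from a pairwise (Potts) sequence model
//   P(x) ~ exp( sum_i h_i(x_i) + sum_{(i,j) in pairs} J_ij(x_i, x_j) )
// with J_ij(a,b) = strength * [a == b] on the declared coupled pairs.
// Each sequence is an independent chain from a random start, run for
// n_sweeps full-site sweeps. Returns n_seq x L states in 1..q.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_potts(int n_seq, int L, int q,
                               IntegerMatrix pairs, NumericVector strength,
                               NumericMatrix fields, int n_sweeps,
                               double seed) {
  IntegerMatrix out(n_seq, L);
  const int npair = pairs.nrow();
  // adjacency: for each site, list of (partner, strength)
  std::vector<std::vector<std::pair<int, double> > > adj(L);
  for (int p = 0; p < npair; ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    adj[i].push_back(std::make_pair(j, strength[p]));
    adj[j].push_back(std::make_pair(i, strength[p]));
  }
  std::vector<double> w(q), x(L, 0.0);
  for (int s = 0; s < n_seq; ++s) {
    XRng rng((uint64_t)seed * 2654435761ULL + (uint64_t)s + 1ULL);
    std::vector<int> st(L);
    for (int i = 0; i < L; ++i) st[i] = rng.below(q);
    for (int sweep = 0; sweep < n_sweeps; ++sweep) {
      for (int i = 0; i < L; ++i) {
        double tot = 0.0;
        for (int a = 0; a < q; ++a) {
          double e = fields(i, a);
          for (size_t t = 0; t < adj[i].size(); ++t)
            if (st[adj[i][t].first] == a) e += adj[i][t].second;
          w[a] = std::exp(e);
          tot += w[a];
        }
        double u = rng.unif() * tot, c = 0.0;
        int pick = q - 1;
        for (int a = 0; a < q; ++a) { c += w[a]; if (u <= c) { pick = a; break; } }
        st[i] = pick;
      }
    }
    for (int i = 0; i < L; ++i) out(s, i) = st[i] + 1;
  }
  return out;
}

// Greedy keep-first redundancy filter: sequence identity computed over
// columns where both sequences are non-gap; a row is dropped if its
// identity to any retained row exceeds max_id.
// [[Rcpp::export]]
LogicalVector cpp_filter_redundancy(IntegerMatrix msa, double max_id,
                                    int gap_state) {
  const int n = msa.nrow(), L = msa.ncol();
  LogicalVector keep(n);
  std::vector<int> kept;
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t t = 0; t < kept.size(); ++t) {
      int j = kept[t], match = 0, tot = 0;
      for (int c = 0; c < L; ++c) {
        int a = msa(i, c), b = msa(j, c);
        if (a == gap_state || b == gap_state) continue;
        ++tot;
        if (a == b) ++match;
      }
      double id = (tot > 0) ? (double)match / tot : 0.0;
      if (id > max_id) { ok = false; break; }
    }
    keep[i] = ok;
    if (ok) kept.push_back(i);
  }
  return keep;
}

// Sequence weights for DCA reweighting: w_i = 1 / #{j : identity(i,j) >= cutoff}
// (identity over all columns, gaps counted as a state, self included).
// [[Rcpp::export]]
NumericVector cpp_seq_weights(IntegerMatrix msa, double cutoff) {
  const int n = msa.nrow(), L = msa.ncol();
  std::vector<int> cnt(n, 1); // self
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int match = 0;
      for (int c = 0; c < L; ++c) if (msa(i, c) == msa(j, c)) ++match;
      if ((double)match / L >= cutoff) { ++cnt[i]; ++cnt[j]; }
    }
  NumericVector w(n);
  for (int i = 0; i < n; ++i) w[i] = 1.0 / cnt[i];
  return w;
}
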