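#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Iterative distance-constraint satisfaction for one conformer.
// Start = reference + uniform displacement within a per-atom bounding box;
// each sweep visits the constraints in a freshly shuffled order and, for any
// pair whose distance falls outside [lo, hi], moves both atoms symmetrically
// along their separation vector onto the nearest bound. Convergence when the
// maximum violation after a full sweep drops below tol.
// [[Rcpp::export]]
List cpp_generate_conformer(NumericMatrix ref, IntegerMatrix pairs,
                            NumericVector lo, NumericVector hi,
                            double box_halfwidth, double tol,
                            int max_iter, double seed) {
  const int n = ref.nrow();
  const int m = pairs.nrow();
  XRng rng((uint64_t)seed);

  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = ref(i, 0) + rng.unif(-box_halfwidth, box_halfwidth);
    y[i] = ref(i, 1) + rng.unif(-box_halfwidth, box_halfwidth);
    z[i] = ref(i, 2) + rng.unif(-box_halfwidth, box_halfwidth);
  }

  std::vector<int> order(m);
  for (int k = 0; k < m; ++k) order[k] = k;

  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // Fisher-Yates reshuffle each sweep from this conformer's own stream
    for (int k = m - 1; k > 0; --k) {
      int j = rng.below(k + 1);
      std::swap(order[k], order[j]);
    }
    for (int k = 0; k < m; ++k) {
      int c = order[k];
      int i = pairs(c, 0) - 1, j = pairs(c, 1) - 1;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double target = d;
      if (d < lo[c]) target = lo[c];
      else if (d > hi[c]) target = hi[c];
      if (target != d) {
        double ux, uy, uz;
        if (d > 1e-12) { ux = dx / d; uy = dy / d; uz = dz / d; }
        else { // coincident atoms: random separation direction
          double th = rng.unif(0.0, 6.283185307179586);
          double cph = rng.unif(-1.0, 1.0), sph = std::sqrt(1.0 - cph * cph);
          ux = sph * std::cos(th); uy = sph * std::sin(th); uz = cph;
        }
        double half = 0.5 * (target - d);
        x[i] -= half * ux; y[i] -= half * uy; z[i] -= half * uz;
        x[j] += half * ux; y[j] += half * uy; z[j] += half * uz;
      }
    }
    // post-sweep violation check, independent of the per-constraint updates
    double maxviol = 0.0;
    for (int c = 0; c < m; ++c) {
      int i = pairs(c, 0) - 1, j = pairs(c, 1) - 1;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double v = 0.0;
      if (d < lo[c]) v = lo[c] - d;
      else if (d > hi[c]) v = d - hi[c];
      if (v > maxviol) maxviol = v;
    }
    if (maxviol < tol) { converged = true; ++iter; break; }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return List::create(_["coords"] = out, _["converged"] = converged,
                      _["iterations"] = iter);
}

// Maximum constraint violation of a coordinate set (post-hoc audit).
// [[Rcpp::export]]
double cpp_max_violation(NumericMatrix coords, IntegerMatrix pairs,
                         NumericVector lo, NumericVector hi) {
  double maxviol = 0.0;
  for (int c = 0; c < pairs.nrow(); ++c) {
    int i = pairs(c, 0) - 1, j = pairs(c, 1) - 1;
    double dx = coords(j, 0) - coords(i, 0);
    double dy = coords(j, 1) - coords(i, 1);
    double dz = coords(j, 2) - coords(i, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double v = 0.0;
    if (d < lo[c]) v = lo[c] - d;
    else if (d > hi[c]) v = d - hi[c];
    if (v > maxviol) maxviol = v;
  }
  return maxviol;
}
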