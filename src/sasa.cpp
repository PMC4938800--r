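#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area. Test points are placed on
// each atom's solvent-expanded sphere with a deterministic golden-spiral
// lattice; a point is accessible if it lies outside every neighbouring
// atom's expanded sphere. Per-atom SASA = exposed fraction * 4*pi*(r+p)^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector out(n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));

  // unit sphere lattice
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  for (int k = 0; k < n_points; ++k) {
    double zc = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - zc * zc));
    double th = golden * k;
    px[k] = rr * std::cos(th);
    py[k] = rr * std::sin(th);
    pz[k] = zc;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  for (int i = 0; i < n; ++i) {
    // neighbours whose expanded spheres can clip atom i's test sphere
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rs = er[i] + er[j];
      if (d2 < rs * rs) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double tx = coords(i, 0) + er[i] * px[k];
      double ty = coords(i, 1) + er[i] * py[k];
      double tz = coords(i, 2) + er[i] * pz[k];
      bool free_pt = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double dx = tx - coords(j, 0);
        double dy = ty - coords(j, 1);
        double dz = tz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    out[i] = 4.0 * M_PI * er[i] * er[i] * ((double)exposed / n_points);
  }
  return out;
}
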