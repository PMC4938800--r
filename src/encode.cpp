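// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Kabsch (least-squares superposition) RMSD between two already-centered
// point sets, via the closed form from the singular values of the cross
// covariance: rmsd^2 = (SSP + SSQ - 2*(s1 + s2 +/- s3)) / n, minus sign when
// the optimal rotation would be improper.
static double kabsch_rmsd_centered(const arma::mat& P, const arma::mat& Q) {
  arma::mat H = P.t() * Q; // 3x3
  arma::vec s;
  arma::mat U, V;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  double tr = s(0) + s(1) + (d < 0 ? -s(2) : s(2));
  double e = arma::accu(P % P) + arma::accu(Q % Q) - 2.0 * tr;
  if (e < 0) e = 0;
  return std::sqrt(e / P.n_rows);
}

static arma::mat centered(const arma::mat& X) {
  arma::rowvec mu = arma::mean(X, 0);
  return X.each_row() - mu;
}

// RMSD of one fragment (k x 3) against each library letter (pre-centered,
// stacked (k*nletters) x 3). Returns the vector of RMSDs.
// [[Rcpp::export]]
NumericVector cpp_fragment_rmsds(NumericMatrix frag, NumericMatrix lib,
                                 int k) {
  arma::mat F = centered(arma::mat(frag.begin(), frag.nrow(), 3, false));
  int nl = lib.nrow() / k;
  arma::mat L(lib.begin(), lib.nrow(), 3, false);
  NumericVector out(nl);
  for (int l = 0; l < nl; ++l)
    out[l] = kabsch_rmsd_centered(F, L.rows(l * k, l * k + k - 1));
  return out;
}

// Encode all fragment windows of all conformers. ca is N x (3*L) with the
// coordinates of conformer r stored (x1..xL, y1..yL, z1..zL). starts are
// 1-based first-residue indices of the admissible windows (chain breaks
// already excluded by the caller). Returns N x nwindows letter indices
// (1-based) of the minimal-RMSD letter; ties resolved to the lowest index.
// [[Rcpp::export]]
IntegerMatrix cpp_encode_ensemble(NumericMatrix ca, int L,
                                  IntegerVector starts,
                                  NumericMatrix lib, int k) {
  const int N = ca.nrow();
  const int nw = starts.size();
  const int nl = lib.nrow() / k;
  arma::mat Lmat(lib.begin(), lib.nrow(), 3, false);
  IntegerMatrix out(N, nw);
  arma::mat F(k, 3);
  for (int r = 0; r < N; ++r) {
    for (int w = 0; w < nw; ++w) {
      int s0 = starts[w] - 1;
      for (int a = 0; a < k; ++a) {
        F(a, 0) = ca(r, s0 + a);
        F(a, 1) = ca(r, L + s0 + a);
        F(a, 2) = ca(r, 2 * L + s0 + a);
      }
      arma::mat Fc = centered(F);
      int best = 0;
      double bestr = R_PosInf;
      for (int l = 0; l < nl; ++l) {
        double rm = kabsch_rmsd_centered(Fc, Lmat.rows(l * k, l * k + k - 1));
        if (rm < bestr - 1e-12) { bestr = rm; best = l; }
      }
      out(r, w) = best + 1;
    }
  }
  return out;
}
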