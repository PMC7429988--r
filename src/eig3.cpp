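#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Batch eigendecomposition of symmetric 3x3 tensors.
// comps: N x 6 matrix, columns (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
// Returns eigenvalues sorted descending (N x 3) and row-flattened
// eigenvector frames (N x 9; columns of the 3x3 frame match eigenvalues).
// Negative eigenvalues are clamped to zero after sorting; the clamp count
// is returned so callers can log it once rather than per voxel.
// [[Rcpp::export]]
List eig3_batch(const NumericMatrix& comps) {
  const int n = comps.nrow();
  NumericMatrix evals(n, 3);
  NumericMatrix evecs(n, 9);
  int n_clamped = 0;
  arma::mat33 A;
  arma::vec3 lam;
  arma::mat33 V;
  for (int i = 0; i < n; ++i) {
    const double dxx = comps(i, 0), dyy = comps(i, 1), dzz = comps(i, 2);
    const double dxy = comps(i, 3), dxz = comps(i, 4), dyz = comps(i, 5);
    if (!std::isfinite(dxx) || !std::isfinite(dyy) || !std::isfinite(dzz) ||
        !std::isfinite(dxy) || !std::isfinite(dxz) || !std::isfinite(dyz)) {
      stop("non-finite tensor component at voxel row %d", i + 1);
    }
    A(0, 0) = dxx; A(0, 1) = dxy; A(0, 2) = dxz;
    A(1, 0) = dxy; A(1, 1) = dyy; A(1, 2) = dyz;
    A(2, 0) = dxz; A(2, 1) = dyz; A(2, 2) = dzz;
    arma::eig_sym(lam, V, A);  // ascending
    bool clamped = false;
    for (int j = 0; j < 3; ++j) {
      double v = lam(2 - j);  // descending
      if (v < 0.0) { v = 0.0; clamped = true; }
      evals(i, j) = v;
      for (int r = 0; r < 3; ++r) evecs(i, 3 * j + r) = V(r, 2 - j);
    }
    if (clamped) ++n_clamped;
  }
  return List::create(_["eigenvalues"] = evals,
                      _["eigenvectors"] = evecs,
                      _["n_clamped"] = n_clamped);
}
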