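#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// 3-D valid convolution (cross-correlation) kernels for the segmentation
// network. Arrays are column-major R arrays:
//   x    (X,  Y,  Z,  Ci)
//   w    (K,  K,  K,  Ci, Co)
//   out  (Xo, Yo, Zo, Co),  Xo = X - K + 1 etc.
// The inner loop is an axpy over the fastest (x) dimension so the compiler
// can vectorise it.

static inline void get_dims4(const NumericVector& a, int d[4]) {
  IntegerVector dd = a.attr("dim");
  if (dd.size() != 4) stop("expected a 4-D array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// [[Rcpp::export]]
NumericVector conv3d_fw(const NumericVector& x, const NumericVector& w,
                        const NumericVector& bias) {
  int xd[4]; get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("expected 5-D weights");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Wci = wd[3], Co = wd[4];
  if (Wci != Ci) stop("input channels (%d) do not match weights (%d)", Ci, Wci);
  const int Xo = X - K1 + 1, Yo = Y - K2 + 1, Zo = Z - K3 + 1;
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("input smaller than kernel");
  NumericVector out(static_cast<R_xlen_t>(Xo) * Yo * Zo * Co);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();

  // z-slice-outer blocking: for each (zo, co) the output slice (Xo*Yo) and
  // the K3 input slices it reads stay cache-resident across the kernel and
  // input-channel accumulation.
  for (int zo = 0; zo < Zo; ++zo) {
    for (int co = 0; co < Co; ++co) {
      const double bv = bias[co];
      double* oslice =
          op + static_cast<R_xlen_t>(Xo) * Yo * (zo + static_cast<R_xlen_t>(Zo) * co);
      for (int i = 0, nn = Xo * Yo; i < nn; ++i) oslice[i] = bv;
      for (int ci = 0; ci < Ci; ++ci) {
        for (int k3 = 0; k3 < K3; ++k3) {
          const double* xslice =
              xp + static_cast<R_xlen_t>(X) * Y * ((zo + k3) + static_cast<R_xlen_t>(Z) * ci);
          for (int k2 = 0; k2 < K2; ++k2)
            for (int k1 = 0; k1 < K1; ++k1) {
              const double wv =
                  wp[k1 + K1 * (k2 + K2 * (k3 + K3 * (ci + Wci * co)))];
              for (int yo = 0; yo < Yo; ++yo) {
                const double* xs = xslice + k1 + static_cast<R_xlen_t>(X) * (yo + k2);
                double* os = oslice + static_cast<R_xlen_t>(Xo) * yo;
                for (int xo = 0; xo < Xo; ++xo) os[xo] += wv * xs[xo];
              }
            }
        }
      }
    }
  }
  return out;
}

// Backward pass: gradients w.r.t. input, weights and bias given the
// gradient at the output. Set need_gx = false for the first layer.
// [[Rcpp::export]]
List conv3d_bw(const NumericVector& x, const NumericVector& w,
               const NumericVector& gout, bool need_gx) {
  int xd[4]; get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Co = wd[4];
  const int Xo = X - K1 + 1, Yo = Y - K2 + 1, Zo = Z - K3 + 1;
  int gd[4]; get_dims4(gout, gd);
  if (gd[0] != Xo || gd[1] != Yo || gd[2] != Zo || gd[3] != Co)
    stop("gradient shape mismatch");

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);

  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* gwp = gw.begin();
  double* gxp = need_gx ? gx.begin() : nullptr;

  for (int co = 0; co < Co; ++co) {
    const double* gbase = gp + static_cast<R_xlen_t>(Xo) * Yo * Zo * co;
    double s = 0.0;
    for (R_xlen_t i = 0, nn = static_cast<R_xlen_t>(Xo) * Yo * Zo; i < nn; ++i)
      s += gbase[i];
    gb[co] = s;
    for (int ci = 0; ci < Ci; ++ci) {
      const double* xc = xp + static_cast<R_xlen_t>(X) * Y * Z * ci;
      double* gxc = need_gx ? gxp + static_cast<R_xlen_t>(X) * Y * Z * ci : nullptr;
      for (int k3 = 0; k3 < K3; ++k3)
        for (int k2 = 0; k2 < K2; ++k2)
          for (int k1 = 0; k1 < K1; ++k1) {
            const R_xlen_t wi =
                k1 + K1 * (k2 + K2 * (k3 + static_cast<R_xlen_t>(K3) * (ci + Ci * co)));
            const double wv = wp[wi];
            double acc = 0.0;
            for (int zo = 0; zo < Zo; ++zo)
              for (int yo = 0; yo < Yo; ++yo) {
                const double* xs =
                    xc + k1 + static_cast<R_xlen_t>(X) * ((yo + k2) + static_cast<R_xlen_t>(Y) * (zo + k3));
                const double* gs = gbase + static_cast<R_xlen_t>(Xo) * (yo + static_cast<R_xlen_t>(Yo) * zo);
                double dot = 0.0;
                if (need_gx) {
                  double* gxs =
                      gxc + k1 + static_cast<R_xlen_t>(X) * ((yo + k2) + static_cast<R_xlen_t>(Y) * (zo + k3));
                  for (int xo = 0; xo < Xo; ++xo) {
                    dot += xs[xo] * gs[xo];
                    gxs[xo] += wv * gs[xo];
                  }
                } else {
                  for (int xo = 0; xo < Xo; ++xo) dot += xs[xo] * gs[xo];
                }
                acc += dot;
              }
            gwp[wi] += acc;
          }
    }
  }
  List res = List::create(_["gw"] = gw, _["gb"] = gb);
  if (need_gx) res["gx"] = gx;
  return res;
}
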