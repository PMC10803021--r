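#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-image ("instance") affine normalisation over the (B*H*W) x C feature
// layout: statistics are computed per image segment and channel, so the
// normalisation is identical in training and inference and independent of
// how images are batched.

// [[Rcpp::export(name = ".inorm_fwd_cpp")]]
List inorm_fwd_cpp(const NumericMatrix& X, const NumericVector& gamma,
                   const NumericVector& beta, int B, double eps) {
  const int C = X.ncol();
  const R_xlen_t N = X.nrow();
  const R_xlen_t seg = N / B;
  NumericMatrix Y(N, C), Xhat(N, C);
  NumericMatrix invstd(B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.begin() + (R_xlen_t)c * N;
    double* yc = Y.begin() + (R_xlen_t)c * N;
    double* hc = Xhat.begin() + (R_xlen_t)c * N;
    const double g = gamma[c], be = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* xs = xc + (R_xlen_t)b * seg;
      double* ys = yc + (R_xlen_t)b * seg;
      double* hs = hc + (R_xlen_t)b * seg;
      double mu = 0.0;
      for (R_xlen_t i = 0; i < seg; ++i) mu += xs[i];
      mu /= seg;
      double var = 0.0;
      for (R_xlen_t i = 0; i < seg; ++i) {
        const double d = xs[i] - mu;
        var += d * d;
      }
      var /= seg;
      const double is = 1.0 / std::sqrt(var + eps);
      invstd(b, c) = is;
      for (R_xlen_t i = 0; i < seg; ++i) {
        const double h = (xs[i] - mu) * is;
        hs[i] = h;
        ys[i] = g * h + be;
      }
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = Xhat, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".inorm_bwd_cpp")]]
List inorm_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Xhat,
                   const NumericMatrix& invstd, const NumericVector& gamma,
                   int B) {
  const int C = dY.ncol();
  const R_xlen_t N = dY.nrow();
  const R_xlen_t seg = N / B;
  NumericMatrix dX(N, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* gc = dY.begin() + (R_xlen_t)c * N;
    const double* hc = Xhat.begin() + (R_xlen_t)c * N;
    double* dc = dX.begin() + (R_xlen_t)c * N;
    const double g = gamma[c];
    double dg = 0.0, db = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* gs = gc + (R_xlen_t)b * seg;
      const double* hs = hc + (R_xlen_t)b * seg;
      double* ds = dc + (R_xlen_t)b * seg;
      double s1 = 0.0, s2 = 0.0;
      for (R_xlen_t i = 0; i < seg; ++i) {
        dg += gs[i] * hs[i];
        db += gs[i];
        s1 += gs[i];
        s2 += gs[i] * hs[i];
      }
      s1 = g * s1 / seg;
      s2 = g * s2 / seg;
      const double is = invstd(b, c);
      for (R_xlen_t i = 0; i < seg; ++i) {
        ds[i] = is * (g * gs[i] - s1 - hs[i] * s2);
      }
    }
    dgamma[c] = dg;
    dbeta[c] = db;
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericMatrix relu_fwd_cpp(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* y = Y.begin();
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0.0 ? x[i] : 0.0;
  return Y;
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericMatrix relu_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Y) {
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* g = dY.begin();
  const double* y = Y.begin();
  double* d = dX.begin();
  const R_xlen_t n = (R_xlen_t)dY.nrow() * dY.ncol();
  for (R_xlen_t i = 0; i < n; ++i) d[i] = y[i] > 0.0 ? g[i] : 0.0;
  return dX;
}
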