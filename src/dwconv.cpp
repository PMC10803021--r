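#include <Rcpp.h>
using namespace Rcpp;

// Feature matrices are (B*H*W) x C, column-major, spatial index p = i + j*H
// (i = row, fastest; matches as.vector() on an R matrix). Image b occupies
// rows b*H*W .. (b+1)*H*W-1. Depthwise kernels are stored as a (k*k) x C
// matrix with tap index t = ki + kj*k.
//
// Output size follows the "same" convention: pad = (k-1)/2,
// Ho = (H + 2*pad - k) / stride + 1, i.e. Ho = H for stride 1 and
// Ho = ceil(H/2) for stride 2 with odd k.

static inline int out_size(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".dw_conv_fwd_cpp")]]
NumericMatrix dw_conv_fwd_cpp(const NumericMatrix& X, const NumericMatrix& W,
                              int B, int H, int Wd, int k, int stride) {
  const int C = X.ncol();
  const int pad = (k - 1) / 2;
  const int Ho = out_size(H, k, pad, stride);
  const int Wo = out_size(Wd, k, pad, stride);
  const int npix_in = H * Wd, npix_out = Ho * Wo;
  NumericMatrix Y(B * npix_out, C);
  const double* xp = X.begin();
  const double* wp = W.begin();
  double* yp = Y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * X.nrow();
    double* yc = yp + (R_xlen_t)c * Y.nrow();
    const double* wc = wp + (R_xlen_t)c * W.nrow();
    for (int b = 0; b < B; ++b) {
      const double* xb = xc + (R_xlen_t)b * npix_in;
      double* yb = yc + (R_xlen_t)b * npix_out;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double w = wc[ki + kj * k];
          if (w == 0.0) continue;
          // input coords: i = oi*stride + ki - pad, j = oj*stride + kj - pad
          const int di = ki - pad, dj = kj - pad;
          int oi0 = 0, oj0 = 0;
          while (oi0 * stride + di < 0) ++oi0;
          while (oj0 * stride + dj < 0) ++oj0;
          int oi1 = Ho - 1, oj1 = Wo - 1;
          while (oi1 >= 0 && oi1 * stride + di > H - 1) --oi1;
          while (oj1 >= 0 && oj1 * stride + dj > Wd - 1) --oj1;
          for (int oj = oj0; oj <= oj1; ++oj) {
            const int j = oj * stride + dj;
            const double* xcol = xb + (R_xlen_t)j * H + di;
            double* ycol = yb + (R_xlen_t)oj * Ho;
            for (int oi = oi0; oi <= oi1; ++oi)
              ycol[oi] += w * xcol[oi * stride];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".dw_conv_bwd_cpp")]]
List dw_conv_bwd_cpp(const NumericMatrix& X, const NumericMatrix& W,
                     const NumericMatrix& dY,
                     int B, int H, int Wd, int k, int stride) {
  const int C = X.ncol();
  const int pad = (k - 1) / 2;
  const int Ho = out_size(H, k, pad, stride);
  const int Wo = out_size(Wd, k, pad, stride);
  const int npix_in = H * Wd, npix_out = Ho * Wo;
  NumericMatrix dX(X.nrow(), C);
  NumericMatrix dW(W.nrow(), C);
  const double* xp = X.begin();
  const double* wp = W.begin();
  const double* gp = dY.begin();
  double* dxp = dX.begin();
  double* dwp = dW.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * X.nrow();
    const double* gc = gp + (R_xlen_t)c * dY.nrow();
    const double* wc = wp + (R_xlen_t)c * W.nrow();
    double* dxc = dxp + (R_xlen_t)c * X.nrow();
    double* dwc = dwp + (R_xlen_t)c * W.nrow();
    for (int b = 0; b < B; ++b) {
      const double* xb = xc + (R_xlen_t)b * npix_in;
      const double* gb = gc + (R_xlen_t)b * npix_out;
      double* dxb = dxc + (R_xlen_t)b * npix_in;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const double w = wc[ki + kj * k];
          const int di = ki - pad, dj = kj - pad;
          int oi0 = 0, oj0 = 0;
          while (oi0 * stride + di < 0) ++oi0;
          while (oj0 * stride + dj < 0) ++oj0;
          int oi1 = Ho - 1, oj1 = Wo - 1;
          while (oi1 >= 0 && oi1 * stride + di > H - 1) --oi1;
          while (oj1 >= 0 && oj1 * stride + dj > Wd - 1) --oj1;
          double acc = 0.0;
          for (int oj = oj0; oj <= oj1; ++oj) {
            const int j = oj * stride + dj;
            const double* xcol = xb + (R_xlen_t)j * H + di;
            double* dxcol = dxb + (R_xlen_t)j * H + di;
            const double* gcol = gb + (R_xlen_t)oj * Ho;
            for (int oi = oi0; oi <= oi1; ++oi) {
              const double g = gcol[oi];
              dxcol[oi * stride] += w * g;
              acc += xcol[oi * stride] * g;
            }
          }
          dwc[ki + kj * k] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dX, _["dw"] = dW);
}
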