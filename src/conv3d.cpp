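// 3D convolution primitives used by the generator/discriminator.
// Arrays are column-major with layout (H, W, D, C); kernels (kh, kw, kd, Ci, Co).
// Implemented as im2col + GEMM so the training loop runs at BLAS speed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Xcol is (N x K): rows index output voxels (ho fast, then wo, then do),
// columns index (hk fast, wk, dk, ci slow) to match the kernel reshape.
static void im2col3(const double* x, const int H, const int W, const int D,
                    const int Ci, const int kh, const int kw, const int kd,
                    const int sh, const int sw, const int sd,
                    const int ph, const int pw, const int pd,
                    const int Ho, const int Wo, const int Do,
                    arma::mat& Xcol) {
  const long N = (long)Ho * Wo * Do;
  long col = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = x + (long)ci * H * W * D;
    for (int dk = 0; dk < kd; ++dk)
      for (int wk = 0; wk < kw; ++wk)
        for (int hk = 0; hk < kh; ++hk, ++col) {
          double* dst = Xcol.colptr(col);
          long n = 0;
          for (int dd = 0; dd < Do; ++dd) {
            const int d = dd * sd - pd + dk;
            const bool dok = d >= 0 && d < D;
            for (int ww = 0; ww < Wo; ++ww) {
              const int w = ww * sw - pw + wk;
              const bool wok = dok && w >= 0 && w < W;
              const double* src = xc + ((long)d * W + w) * H;
              for (int hh = 0; hh < Ho; ++hh, ++n) {
                const int h = hh * sh - ph + hk;
                dst[n] = (wok && h >= 0 && h < H) ? src[h] : 0.0;
              }
            }
          }
          if (n != N) Rcpp::stop("im2col internal size mismatch");
        }
  }
}

// Scatter-add transpose of im2col3.
static void col2im3(const arma::mat& Gcol, const int H, const int W, const int D,
                    const int Ci, const int kh, const int kw, const int kd,
                    const int sh, const int sw, const int sd,
                    const int ph, const int pw, const int pd,
                    const int Ho, const int Wo, const int Do,
                    double* gx) {
  long col = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    double* xc = gx + (long)ci * H * W * D;
    for (int dk = 0; dk < kd; ++dk)
      for (int wk = 0; wk < kw; ++wk)
        for (int hk = 0; hk < kh; ++hk, ++col) {
          const double* src = Gcol.colptr(col);
          long n = 0;
          for (int dd = 0; dd < Do; ++dd) {
            const int d = dd * sd - pd + dk;
            const bool dok = d >= 0 && d < D;
            for (int ww = 0; ww < Wo; ++ww) {
              const int w = ww * sw - pw + wk;
              const bool wok = dok && w >= 0 && w < W;
              double* dst = xc + ((long)d * W + w) * H;
              for (int hh = 0; hh < Ho; ++hh, ++n) {
                const int h = hh * sh - ph + hk;
                if (wok && h >= 0 && h < H) dst[h] += src[n];
              }
            }
          }
        }
  }
}

// [[Rcpp::export(rng = false)]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector b,
                                 IntegerVector stride, IntegerVector pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], Ci = xdim[3];
  const int kh = wdim[0], kw = wdim[1], kd = wdim[2], Co = wdim[4];
  if (wdim[3] != Ci) stop("conv3d: input has %d channels, kernel expects %d", Ci, wdim[3]);
  const int Ho = out_len(H, kh, stride[0], pad[0]);
  const int Wo = out_len(W, kw, stride[1], pad[1]);
  const int Do = out_len(D, kd, stride[2], pad[2]);
  if (Ho < 1 || Wo < 1 || Do < 1) stop("conv3d: output would be empty");
  const long N = (long)Ho * Wo * Do;
  const long K = (long)kh * kw * kd * Ci;

  arma::mat Xcol(N, K);
  im2col3(x.begin(), H, W, D, Ci, kh, kw, kd,
          stride[0], stride[1], stride[2], pad[0], pad[1], pad[2],
          Ho, Wo, Do, Xcol);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat Y = Xcol * Wm;
  Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Co, false, true);

  NumericVector out(N * Co);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(Ho, Wo, Do, Co);
  return out;
}

// [[Rcpp::export(rng = false)]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector gy,
                         IntegerVector stride, IntegerVector pad) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], Ci = xdim[3];
  const int kh = wdim[0], kw = wdim[1], kd = wdim[2], Co = wdim[4];
  const int Ho = out_len(H, kh, stride[0], pad[0]);
  const int Wo = out_len(W, kw, stride[1], pad[1]);
  const int Do = out_len(D, kd, stride[2], pad[2]);
  const long N = (long)Ho * Wo * Do;
  const long K = (long)kh * kw * kd * Ci;
  if ((long)gy.size() != N * Co) stop("conv3d backward: gradient size mismatch");

  arma::mat Xcol(N, K);
  im2col3(x.begin(), H, W, D, Ci, kh, kw, kd,
          stride[0], stride[1], stride[2], pad[0], pad[1], pad[2],
          Ho, Wo, Do, Xcol);
  const arma::mat Gy(const_cast<double*>(gy.begin()), N, Co, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);

  arma::mat Gw = Xcol.t() * Gy;             // K x Co
  arma::rowvec Gb = arma::sum(Gy, 0);       // 1 x Co
  arma::mat Gcol = Gy * Wm.t();             // N x K

  NumericVector gx(x.size());
  std::fill(gx.begin(), gx.end(), 0.0);
  col2im3(Gcol, H, W, D, Ci, kh, kw, kd,
          stride[0], stride[1], stride[2], pad[0], pad[1], pad[2],
          Ho, Wo, Do, gx.begin());
  gx.attr("dim") = xdim;

  NumericVector gwv(Gw.begin(), Gw.end());
  gwv.attr("dim") = wdim;
  NumericVector gbv(Gb.begin(), Gb.end());
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}
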