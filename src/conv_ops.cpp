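// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Tensors are numeric arrays with dim = c(H, W, N, C): row index fastest,
// channels slowest. Convolution is im2col + GEMM: the patch matrix is
// (H*W*N) x (k*k*C) with row r = h + H*w + H*W*n and column
// col = ki + k*kj + k*k*c, matching the (k, k, C_in, C_out) flattening of
// the weight matrix. Zero padding of (k-1)/2 keeps spatial size unchanged.
//
// The arithmetic type is templated: float storage feeds sgemm, which on the
// skinny shapes of this workload runs ~3x faster than dgemm; the double
// instantiation provides an exact path that finite-difference gradient
// tests (and anyone wanting reference numerics) can select per model.

template <typename T>
static void im2col_t(const double *px, int H, int W, int N, int C, int k,
                     arma::Mat<T> &M) {
  const int p = (k - 1) / 2;
  const R_xlen_t R = (R_xlen_t)H * W * N;
  T *pm = M.memptr();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)k * kj + (R_xlen_t)k * k * c;
        T *dst0 = pm + col * R;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int iw = w + kj - p;
            T *dst = dst0 + (R_xlen_t)H * w + (R_xlen_t)H * W * n;
            if (iw < 0 || iw >= W) {
              for (int h = 0; h < H; ++h) dst[h] = (T)0;
              continue;
            }
            const double *src = px + (R_xlen_t)H * iw + (R_xlen_t)H * W * n +
                                (R_xlen_t)H * W * N * c;
            const int h0 = std::max(0, p - ki);      // ih = h + ki - p
            const int h1 = std::min(H, H + p - ki);
            for (int h = 0; h < h0; ++h) dst[h] = (T)0;
            for (int h = h1; h < H; ++h) dst[h] = (T)0;
            const double *s2 = src + ki - p;
            for (int h = h0; h < h1; ++h) dst[h] = (T)s2[h];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add patch-matrix gradients back to the input.
template <typename T>
static NumericVector col2im_t(const arma::Mat<T> &M, int H, int W, int N,
                              int C, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t R = (R_xlen_t)H * W * N;
  NumericVector x((R_xlen_t)H * W * N * C);
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  const T *pm = M.memptr();
  double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const R_xlen_t col = ki + (R_xlen_t)k * kj + (R_xlen_t)k * k * c;
        const T *src0 = pm + col * R;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int iw = w + kj - p;
            if (iw < 0 || iw >= W) continue;
            const T *src = src0 + (R_xlen_t)H * w + (R_xlen_t)H * W * n;
            double *dst = px + (R_xlen_t)H * iw + (R_xlen_t)H * W * n +
                          (R_xlen_t)H * W * N * c;
            const int h0 = std::max(0, p - ki);
            const int h1 = std::min(H, H + p - ki);
            double *d2 = dst + ki - p;
            for (int h = h0; h < h1; ++h) d2[h] += (double)src[h];
          }
        }
      }
    }
  }
  return x;
}

template <typename T>
static NumericVector conv_fw_t(const NumericVector &x, const NumericMatrix &w,
                               const NumericVector &b, int k, double slope,
                               bool linear) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  const int Cout = w.ncol();
  const R_xlen_t R = (R_xlen_t)H * W * N;
  arma::Mat<T> M(R, (R_xlen_t)k * k * C);
  im2col_t<T>(x.begin(), H, W, N, C, k, M);
  arma::Mat<T> Wf(w.nrow(), Cout);
  std::copy(w.begin(), w.end(), Wf.memptr());
  arma::Mat<T> Y = M * Wf;
  const T sl = (T)slope;
  NumericVector out(R * Cout);
  out.attr("dim") = IntegerVector::create(H, W, N, Cout);
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const T bc = (T)b[co];
    const T *py = Y.colptr(co);
    double *pd = po + R * co;
    if (linear) {
      for (R_xlen_t i = 0; i < R; ++i) pd[i] = (double)(py[i] + bc);
    } else {
      for (R_xlen_t i = 0; i < R; ++i) {
        T v = py[i] + bc;
        pd[i] = (double)(v < (T)0 ? v * sl : v);
      }
    }
  }
  return out;
}

template <typename T>
static List conv_bw_t(const NumericVector &x, const NumericVector &y,
                      const NumericMatrix &w, const NumericVector &dy, int k,
                      double slope, bool linear) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  const int Cout = w.ncol();
  const R_xlen_t R = (R_xlen_t)H * W * N;
  arma::Mat<T> dY(R, Cout);
  const T sl = (T)slope;
  // Leaky ReLU is sign-preserving, so the pre-activation sign (and hence the
  // local slope) can be read off the cached post-activation output.
  for (int co = 0; co < Cout; ++co) {
    const double *pdy = dy.begin() + R * co;
    const double *pyy = y.begin() + R * co;
    T *pc = dY.colptr(co);
    if (linear)
      for (R_xlen_t i = 0; i < R; ++i) pc[i] = (T)pdy[i];
    else
      for (R_xlen_t i = 0; i < R; ++i)
        pc[i] = (T)(pyy[i] < 0 ? pdy[i] * sl : pdy[i]);
  }
  arma::Mat<T> M(R, (R_xlen_t)k * k * C);
  im2col_t<T>(x.begin(), H, W, N, C, k, M);
  arma::Mat<T> Wf(w.nrow(), Cout);
  std::copy(w.begin(), w.end(), Wf.memptr());
  arma::Mat<T> dW = M.t() * dY;
  arma::Mat<T> dM = dY * Wf.t();
  NumericMatrix dWout(w.nrow(), Cout);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) db[co] = arma::accu(dY.col(co));
  NumericVector dx = col2im_t<T>(dM, H, W, N, C, k);
  return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = db);
}

// [[Rcpp::export(name = ".conv_fw_cpp")]]
NumericVector conv_fw_cpp(NumericVector x, NumericMatrix w, NumericVector b,
                          int k, double slope, bool linear, bool exact) {
  return exact ? conv_fw_t<double>(x, w, b, k, slope, linear)
               : conv_fw_t<float>(x, w, b, k, slope, linear);
}

// [[Rcpp::export(name = ".conv_bw_cpp")]]
List conv_bw_cpp(NumericVector x, NumericVector y, NumericMatrix w,
                 NumericVector dy, int k, double slope, bool linear,
                 bool exact) {
  return exact ? conv_bw_t<double>(x, y, w, dy, k, slope, linear)
               : conv_bw_t<float>(x, y, w, dy, k, slope, linear);
}

// 2x2 max pooling with stride 2; records the argmax (0..3, ki + 2*kj) so the
// backward pass routes the gradient to a single input pixel per window.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * N * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  RawVector idx((R_xlen_t)Ho * Wo * N * C);
  const double *px = x.begin();
  double *py = y.begin();
  Rbyte *pi = idx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          const R_xlen_t base = (R_xlen_t)2 * ho + (R_xlen_t)H * 2 * wo +
                                (R_xlen_t)H * W * n + (R_xlen_t)H * W * N * c;
          double best = px[base];
          int arg = 0;
          double v = px[base + 1];
          if (v > best) { best = v; arg = 1; }
          v = px[base + H];
          if (v > best) { best = v; arg = 2; }
          v = px[base + H + 1];
          if (v > best) { best = v; arg = 3; }
          py[o] = best;
          pi[o] = (Rbyte)arg;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw_cpp(NumericVector dy, RawVector idx, int H, int W,
                              int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * N * C);
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  const double *pd = dy.begin();
  const Rbyte *pi = idx.begin();
  double *px = dx.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          const int arg = pi[o];
          const R_xlen_t base = (R_xlen_t)2 * ho + (R_xlen_t)H * 2 * wo +
                                (R_xlen_t)H * W * n + (R_xlen_t)H * W * N * c;
          px[base + (arg & 1) + H * (arg >> 1)] += pd[o];
        }
  return dx;
}
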