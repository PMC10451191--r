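// Low-level dense kernels for the segmentation network.
//
// Array layout convention (matches R's column-major order):
//   feature maps  : dim = c(H, W, C, N)
//   conv kernels  : dim = c(kh, kw, Cin, Cout)
// All kernels are written for small desk-scale problems; the heavy lifting
// (the im2col GEMM) is delegated to BLAS through Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// `col` is stored with patches as rows so the inner ho loop writes and reads
// contiguous memory; the GEMM is then Y = col * Wm. `ldc` is the leading
// dimension of the full column matrix (P for a single sample, P*N when all
// samples are stacked into one (P*N) x K matrix).
static void im2col(const double* xs, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* colbase, size_t ldc) {
  int P = Ho * Wo;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        double* cc = colbase + ldc * r;
        for (int wo = 0; wo < Wo; ++wo) {
          int wx = wo * stride - pad + kj;
          if (wx < 0 || wx >= W) continue;
          const double* xcol = xs + (size_t)H * (wx + (size_t)W * ci);
          int ho_lo = 0, ho_hi = Ho;  // valid range of ho given padding
          while (ho_lo < Ho && ho_lo * stride - pad + ki < 0) ++ho_lo;
          while (ho_hi > ho_lo && (ho_hi - 1) * stride - pad + ki >= H) --ho_hi;
          double* dst = cc + ho_lo + (size_t)Ho * wo;
          const double* src = xcol + ho_lo * stride - pad + ki;
          if (stride == 1) {
            memcpy(dst, src, sizeof(double) * (ho_hi - ho_lo));
          } else {
            for (int ho = ho_lo; ho < ho_hi; ++ho)
              dst[ho - ho_lo] = src[(size_t)(ho - ho_lo) * stride];
          }
        }
      }
    }
  }
  (void)P;
}

// inverse of im2col with accumulation into dx (same layout conventions)
static void col2im_acc(const double* colbase, size_t ldc, int H, int W, int Cin,
                       int kh, int kw, int stride, int pad, int Ho, int Wo,
                       double* dxs) {
  for (int ci = 0; ci < Cin; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        const double* dc = colbase + ldc * r;
        for (int wo = 0; wo < Wo; ++wo) {
          int wx = wo * stride - pad + kj;
          if (wx < 0 || wx >= W) continue;
          double* dxcol = dxs + (size_t)H * (wx + (size_t)W * ci);
          int ho_lo = 0, ho_hi = Ho;
          while (ho_lo < Ho && ho_lo * stride - pad + ki < 0) ++ho_lo;
          while (ho_hi > ho_lo && (ho_hi - 1) * stride - pad + ki >= H) --ho_hi;
          const double* src = dc + ho_lo + (size_t)Ho * wo;
          double* dst = dxcol + ho_lo * stride - pad + ki;
          if (stride == 1) {
            for (int t = 0; t < ho_hi - ho_lo; ++t) dst[t] += src[t];
          } else {
            for (int ho = ho_lo; ho < ho_hi; ++ho)
              dst[(size_t)(ho - ho_lo) * stride] += src[ho - ho_lo];
          }
        }
      }
}

// forward that also returns the stacked im2col matrix ((P*N) x K, samples
// contiguous within each column) for reuse in the backward pass; all samples
// share one GEMM.
// [[Rcpp::export]]
List cpp_conv2d_fwd_cache(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: kernel expects %d input channels, got %d", wd[2], Cin);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector colall((size_t)P * K * N);
  colall.attr("dim") = IntegerVector::create(P, K, N);
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    double* colptr = colall.begin() + (size_t)n * P * K;
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, stride, pad,
           Ho, Wo, colptr, P);
    arma::mat col(colptr, P, K, false);
    arma::mat Y(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    Y = col * Wm;
    if (b.size() > 0)
      for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return List::create(_["y"] = y, _["col"] = colall);
}

// backward using the cached stacked im2col matrix; dx is skipped when the
// input does not need a gradient (e.g. the stem convolution on raw images)
// [[Rcpp::export]]
List cpp_conv2d_bwd_cache(NumericVector colall, NumericVector w, NumericVector gy,
                          IntegerVector xdim, int stride, int pad, bool has_bias,
                          bool want_dx) {
  IntegerVector wd = w.attr("dim");
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  NumericVector db(has_bias ? Cout : 0);
  NumericVector dx(want_dx ? (size_t)H * W * Cin * N : 0);
  if (want_dx) dx.attr("dim") = xdim;
  arma::mat dcol(P, K);
  for (int n = 0; n < N; ++n) {
    arma::mat col(const_cast<double*>(colall.begin()) + (size_t)n * P * K, P, K, false);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * P * Cout, P, Cout, false);
    dWm += col.t() * GY;
    if (has_bias)
      for (int co = 0; co < Cout; ++co) db[co] += arma::accu(GY.col(co));
    if (want_dx) {
      dcol = GY * Wm.t();
      col2im_acc(dcol.memptr(), P, H, W, Cin, kh, kw, stride, pad, Ho, Wo,
                 dx.begin() + (size_t)n * H * W * Cin);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: kernel expects %d input channels, got %d", wd[2], Cin);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Cin;
    col.zeros();
    im2col(xs, H, W, Cin, kh, kw, stride, pad, Ho, Wo, col.memptr(), P);
    arma::mat Y(y.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    Y = col * Wm;
    if (b.size() > 0)
      for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(w.begin(), K, Cout, false);

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat col(P, K), dcol(P, K);

  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Cin;
    col.zeros();
    im2col(xs, H, W, Cin, kh, kw, stride, pad, Ho, Wo, col.memptr(), P);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * P * Cout, P, Cout, false);
    dWm += col.t() * GY;
    if (has_bias)
      for (int co = 0; co < Cout; ++co) db[co] += arma::accu(GY.col(co));
    dcol = GY * Wm.t();
    // col2im accumulate
    double* dxs = dx.begin() + (size_t)n * H * W * Cin;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          int r = ki + kh * (kj + kw * ci);
          const double* dc = dcol.colptr(r);
          for (int wo = 0; wo < Wo; ++wo) {
            int wx = wo * stride - pad + kj;
            if (wx < 0 || wx >= W) continue;
            double* dxcol = dxs + (size_t)H * (wx + (size_t)W * ci);
            int ho_lo = 0, ho_hi = Ho;
            while (ho_lo < Ho && ho_lo * stride - pad + ki < 0) ++ho_lo;
            while (ho_hi > ho_lo && (ho_hi - 1) * stride - pad + ki >= H) --ho_hi;
            const double* src = dc + ho_lo + (size_t)Ho * wo;
            double* dst = dxcol + ho_lo * stride - pad + ki;
            if (stride == 1) {
              for (int t = 0; t < ho_hi - ho_lo; ++t) dst[t] += src[t];
            } else {
              for (int ho = ho_lo; ho < ho_hi; ++ho)
                dst[(size_t)(ho - ho_lo) * stride] += src[ho - ho_lo];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- per-channel reductions and broadcasts over (H, W, C, N) arrays --------

// [[Rcpp::export]]
NumericVector cpp_ch_sum(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector out(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += *p++;
      out[c] += s;
    }
  return out;
}

// per-channel sum of an elementwise product
// [[Rcpp::export]]
NumericVector cpp_ch_dot(NumericVector x, NumericVector y) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector out(C);
  const double* p = x.begin();
  const double* q = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += (*p++) * (*q++);
      out[c] += s;
    }
  return out;
}

// y = a_c * x + b_c, broadcasting per-channel coefficients
// [[Rcpp::export]]
NumericVector cpp_bc_affine(NumericVector x, NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* p = x.begin();
  double* o = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) *o++ = ac * (*p++) + bc;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* o = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) o[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector y) {
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  const double* pg = g.begin();
  const double* py = y.begin();
  double* o = dx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) o[i] = py[i] > 0 ? pg[i] : 0;
  return dx;
}

// fused normalization forward: xhat = (x - mu_c) * istd_c, y = g_c*xhat + b_c
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector mu, NumericVector istd,
                NumericVector gamma, NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = xd;
  y.attr("dim") = xd;
  const double* p = x.begin();
  double* xh = xhat.begin();
  double* o = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double m = mu[c], s = istd[c], gc = gamma[c], bc = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        double h = (*p++ - m) * s;
        *xh++ = h;
        *o++ = gc * h + bc;
      }
    }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// fused normalization backward. training mode backpropagates through the
// batch statistics; eval mode treats them as constants.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector g, NumericVector xhat, NumericVector gamma,
                NumericVector istd, bool training) {
  IntegerVector xd = g.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  {
    const double* pg = g.begin();
    const double* xh = xhat.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double s1 = 0, s2 = 0;
        for (size_t i = 0; i < HW; ++i) {
          s1 += (*pg) * (*xh);
          s2 += *pg;
          ++pg; ++xh;
        }
        dgamma[c] += s1;
        dbeta[c] += s2;
      }
  }
  NumericVector dx(g.size());
  dx.attr("dim") = xd;
  const double* pg = g.begin();
  const double* xh = xhat.begin();
  double* o = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double k = gamma[c] * istd[c];
      if (training) {
        double a = dbeta[c] / M, b = dgamma[c] / M;
        for (size_t i = 0; i < HW; ++i) {
          *o++ = k * (*pg - a - (*xh) * b);
          ++pg; ++xh;
        }
      } else {
        for (size_t i = 0; i < HW; ++i) {
          *o++ = k * (*pg);
          ++pg; ++xh;
        }
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// fused channel-gate forward:
//   xhat = (x - mu_c) istd_c; gate = sigmoid(slope_c xhat + shift_c); y = x * gate
// [[Rcpp::export]]
List cpp_ca_fwd(NumericVector x, NumericVector mu, NumericVector istd,
                NumericVector slope, NumericVector shift) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector xhat(x.size()), gate(x.size()), y(x.size());
  xhat.attr("dim") = xd;
  gate.attr("dim") = xd;
  y.attr("dim") = xd;
  const double* p = x.begin();
  double* xh = xhat.begin();
  double* gt = gate.begin();
  double* o = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double m = mu[c], s = istd[c], sl = slope[c], sh = shift[c];
      for (size_t i = 0; i < HW; ++i) {
        double xv = *p++;
        double h = (xv - m) * s;
        double gv = 1.0 / (1.0 + std::exp(-(sl * h + sh)));
        *xh++ = h;
        *gt++ = gv;
        *o++ = xv * gv;
      }
    }
  return List::create(_["xhat"] = xhat, _["gate"] = gate, _["y"] = y);
}

// fused channel-gate backward: dz = G x gate (1-gate) is recomputed in both
// passes instead of materialized.
// [[Rcpp::export]]
List cpp_ca_bwd(NumericVector g, NumericVector x, NumericVector xhat,
                NumericVector gate, NumericVector slope, NumericVector istd,
                bool training) {
  IntegerVector xd = g.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  double M = (double)HW * N;
  NumericVector dslope(C), dshift(C);
  {
    const double* pg = g.begin();
    const double* px = x.begin();
    const double* xh = xhat.begin();
    const double* gt = gate.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double s1 = 0, s2 = 0;
        for (size_t i = 0; i < HW; ++i) {
          double dz = (*pg) * (*px) * (*gt) * (1.0 - *gt);
          s1 += dz * (*xh);
          s2 += dz;
          ++pg; ++px; ++xh; ++gt;
        }
        dslope[c] += s1;
        dshift[c] += s2;
      }
  }
  NumericVector dx(g.size());
  dx.attr("dim") = xd;
  const double* pg = g.begin();
  const double* px = x.begin();
  const double* xh = xhat.begin();
  const double* gt = gate.begin();
  double* o = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double sl = slope[c], s = istd[c];
      double a = training ? s * sl * dshift[c] / M : 0.0;
      double b = training ? s * dslope[c] / M : 0.0;
      for (size_t i = 0; i < HW; ++i) {
        double dz = (*pg) * (*px) * (*gt) * (1.0 - *gt);
        double dxv = (*pg) * (*gt) + sl * s * dz;
        if (training) dxv -= a + (*xh) * b * sl;
        *o++ = dxv;
        ++pg; ++px; ++xh; ++gt;
      }
    }
  return List::create(_["dx"] = dx, _["dslope"] = dslope, _["dshift"] = dshift);
}

// in-place Adam update (p, m, v are owned by the training loop)
// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double beta1, double beta2,
                   double eps, double c1, double c2) {
  double* pp = p.begin();
  const double* pg = g.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    pm[i] = beta1 * pm[i] + (1 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}

// y = a_c * x + b_c * z (two arrays, per-channel coefficients)
// [[Rcpp::export]]
NumericVector cpp_bc_axpby(NumericVector x, NumericVector z,
                           NumericVector a, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  size_t HW = (size_t)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* p = x.begin();
  const double* q = z.begin();
  double* o = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) *o++ = ac * (*p++) + bc * (*q++);
    }
  return y;
}

// Transposed 2x2 stride-2 convolution (exact inverse geometry of a 2x
// downsampling): y[2h+ki, 2w+kj, co] = sum_ci x[h,w,ci] * w[ki,kj,ci,co]
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  NumericVector y((size_t)4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Cin;
    double* ys = y.begin() + (size_t)n * 4 * H * W * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int kj = 0; kj < 2; ++kj)
          for (int ki = 0; ki < 2; ++ki) {
            double wv = w[ki + 2 * (kj + 2 * (ci + Cin * co))];
            if (wv == 0.0) continue;
            for (int wx = 0; wx < W; ++wx)
              for (int hx = 0; hx < H; ++hx)
                ys[(2 * hx + ki) + (size_t)2 * H * ((2 * wx + kj) + (size_t)2 * W * co)] +=
                  wv * xs[hx + (size_t)H * (wx + (size_t)W * ci)];
          }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * Cin;
    const double* gs = gy.begin() + (size_t)n * 4 * H * W * Cout;
    double* dxs = dx.begin() + (size_t)n * H * W * Cin;
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int kj = 0; kj < 2; ++kj)
          for (int ki = 0; ki < 2; ++ki) {
            int widx = ki + 2 * (kj + 2 * (ci + Cin * co));
            double wv = w[widx], dwv = 0.0;
            for (int wx = 0; wx < W; ++wx)
              for (int hx = 0; hx < H; ++hx) {
                double g = gs[(2 * hx + ki) + (size_t)2 * H * ((2 * wx + kj) + (size_t)2 * W * co)];
                double xv = xs[hx + (size_t)H * (wx + (size_t)W * ci)];
                dxs[hx + (size_t)H * (wx + (size_t)W * ci)] += wv * g;
                dwv += xv * g;
              }
            dw[widx] += dwv;
          }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 stride-2 max pooling; returns pooled values and 0-based argmax indices
// into the input vector for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          // column-major output order is (ho fastest); match by iterating ho inner
          size_t oi = (size_t)ho + Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          int h0 = 2 * ho, w0 = 2 * wo;
          double best = xs[h0 + H * w0];
          size_t bi = h0 + (size_t)H * w0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = xs[(h0 + di) + (size_t)H * (w0 + dj)];
              if (v > best) { best = v; bi = (h0 + di) + (size_t)H * (w0 + dj); }
            }
          y[oi] = best;
          idx[oi] = (int)(base + bi);
        }
      (void)o;
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) dx[idx[i]] += gy[i];
  return dx;
}

static void up2_coeffs(int Hi, std::vector<int>& i0, std::vector<int>& i1,
                       std::vector<double>& t) {
  int Ho = 2 * Hi;
  i0.resize(Ho); i1.resize(Ho); t.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > Hi - 1) s = Hi - 1;
    int f = (int)std::floor(s);
    i0[i] = f;
    i1[i] = std::min(f + 1, Hi - 1);
    t[i] = s - f;
  }
}

// Bilinear 2x upsampling (half-pixel centres, edge clamped).
// [[Rcpp::export]]
NumericVector cpp_up2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::vector<int> i0, i1, j0, j1;
  std::vector<double> t, u;
  up2_coeffs(H, i0, i1, t);
  up2_coeffs(W, j0, j1, u);
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* ys = y.begin() + (size_t)4 * H * W * (c + (size_t)C * n);
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i) {
          double a = (1 - t[i]) * (1 - u[j]) * xs[i0[i] + (size_t)H * j0[j]]
                   + t[i] * (1 - u[j]) * xs[i1[i] + (size_t)H * j0[j]]
                   + (1 - t[i]) * u[j] * xs[i0[i] + (size_t)H * j1[j]]
                   + t[i] * u[j] * xs[i1[i] + (size_t)H * j1[j]];
          ys[i + (size_t)2 * H * j] = a;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_up2_bwd(NumericVector gy, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  std::vector<int> i0, i1, j0, j1;
  std::vector<double> t, u;
  up2_coeffs(H, i0, i1, t);
  up2_coeffs(W, j0, j1, u);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gs = gy.begin() + (size_t)4 * H * W * (c + (size_t)C * n);
      double* dxs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i) {
          double g = gs[i + (size_t)2 * H * j];
          dxs[i0[i] + (size_t)H * j0[j]] += (1 - t[i]) * (1 - u[j]) * g;
          dxs[i1[i] + (size_t)H * j0[j]] += t[i] * (1 - u[j]) * g;
          dxs[i0[i] + (size_t)H * j1[j]] += (1 - t[i]) * u[j] * g;
          dxs[i1[i] + (size_t)H * j1[j]] += t[i] * u[j] * g;
        }
    }
  return dx;
}
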