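// Convolutional network primitives used by the split ResNet18 classifier and
// the conditional GAN. All heavy arithmetic runs in single precision through
// BLAS sgemm (im2col lowering); inputs/outputs cross the R boundary as double
// arrays laid out (H, W, C, N) column-major, matching R's array order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fvec as_fvec(const NumericVector& x) {
  arma::fvec out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

// Gather im2col block for samples [n0, n0+nc) into col (HoWo*nc x K*K*C).
// Column index c = kh + K*kw + K*K*ci; row index r = ho + Ho*wo + Ho*Wo*local.
// valid output range [lo, hi) such that 0 <= o*stride + k - pad < limit
static inline void valid_range(int k, int pad, int stride, int limit,
                               int out, int& lo, int& hi) {
  int off = k - pad;
  lo = off < 0 ? (-off + stride - 1) / stride : 0;
  hi = std::min(out, off < limit ? (limit - off + stride - 1) / stride : 0);
  if (hi < lo) hi = lo;
}

static void im2col(const float* x, int H, int W, int C, int n0, int nc,
                   int K, int stride, int pt, int pl, int Ho, int Wo,
                   arma::fmat& col) {
  const int HoWo = Ho * Wo;
  col.zeros();
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < K; ++kw) {
      int wlo, whi;
      valid_range(kw, pl, stride, W, Wo, wlo, whi);
      for (int kh = 0; kh < K; ++kh) {
        int hlo, hhi;
        valid_range(kh, pt, stride, H, Ho, hlo, hhi);
        const int cc = kh + K * kw + K * K * ci;
        float* dst = col.colptr(cc);
        for (int nl = 0; nl < nc; ++nl) {
          const float* xs = x + (size_t)H * W * (ci + (size_t)C * (n0 + nl));
          for (int wo = wlo; wo < whi; ++wo) {
            const float* xcol = xs + (size_t)H * (wo * stride + kw - pl)
                                + (kh - pt);
            float* d = dst + (size_t)HoWo * nl + (size_t)Ho * wo;
            if (stride == 1) {
              std::copy(xcol + hlo, xcol + hhi, d + hlo);
            } else {
              for (int ho = hlo; ho < hhi; ++ho)
                d[ho] = xcol[(size_t)ho * stride];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of dcol (HoWo*nc x K*K*C) back into dx (col2im transpose).
static void col2im(const arma::fmat& dcol, float* dx, int H, int W, int C,
                   int n0, int nc, int K, int stride, int pt, int pl,
                   int Ho, int Wo) {
  const int HoWo = Ho * Wo;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < K; ++kw) {
      int wlo, whi;
      valid_range(kw, pl, stride, W, Wo, wlo, whi);
      for (int kh = 0; kh < K; ++kh) {
        int hlo, hhi;
        valid_range(kh, pt, stride, H, Ho, hlo, hhi);
        const int cc = kh + K * kw + K * K * ci;
        const float* src = dcol.colptr(cc);
        for (int nl = 0; nl < nc; ++nl) {
          float* xs = dx + (size_t)H * W * (ci + (size_t)C * (n0 + nl));
          for (int wo = wlo; wo < whi; ++wo) {
            float* xcol = xs + (size_t)H * (wo * stride + kw - pl)
                          + (kh - pt);
            const float* s = src + (size_t)HoWo * nl + (size_t)Ho * wo;
            for (int ho = hlo; ho < hhi; ++ho)
              xcol[(size_t)ho * stride] += s[ho];
          }
        }
      }
    }
  }
}

static int chunk_size(int N, int HoWo, int KKC) {
  // keep the im2col buffer around 32 MB of floats
  double per = (double)HoWo * KKC;
  int nc = (int)std::max(1.0, std::floor(8.0e6 / per));
  return std::min(N, nc);
}

// act: 0 = identity, 1 = leaky ReLU (slope 0 gives ReLU), 2 = tanh
static inline float apply_act(float v, int act, float slope) {
  if (act == 1) return v > 0 ? v : slope * v;
  if (act == 2) return std::tanh(v);
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, IntegerVector xdim,
                          NumericVector w, IntegerVector wdim,
                          NumericVector bias, int stride,
                          int pt, int pb, int pl, int pr,
                          int act = 0, double slope = 0.0) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cout = wdim[3];
  if (wdim[2] != C) stop("channel mismatch between input and filter");
  const int Ho = (H + pt + pb - K) / stride + 1;
  const int Wo = (W + pl + pr - K) / stride + 1;
  const int HoWo = Ho * Wo, KKC = K * K * C;

  arma::fvec xf = as_fvec(x);
  arma::fmat Wm(as_fvec(w).memptr(), KKC, Cout);      // copy into shape
  arma::fvec bf = as_fvec(bias);

  NumericVector y((R_xlen_t)HoWo * Cout * N);
  const int nc0 = chunk_size(N, HoWo, KKC);
  arma::fmat col(HoWo * nc0, KKC);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    const int nc = std::min(nc0, N - n0);
    if (nc != nc0) col.set_size(HoWo * nc, KKC);
    im2col(xf.memptr(), H, W, C, n0, nc, K, stride, pt, pl, Ho, Wo, col);
    arma::fmat Y = col * Wm;                          // (HoWo*nc) x Cout
    for (int co = 0; co < Cout; ++co) {
      const float* src = Y.colptr(co);
      const float b = bf.n_elem ? bf[co] : 0.0f;
      for (int nl = 0; nl < nc; ++nl) {
        double* dst = REAL(y) + (size_t)HoWo * (co + (size_t)Cout * (n0 + nl));
        const float* s = src + (size_t)HoWo * nl;
        for (int i = 0; i < HoWo; ++i)
          dst[i] = (double)apply_act(s[i] + b, act, (float)slope);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bw_data(NumericVector dy, IntegerVector ydim,
                               NumericVector w, IntegerVector wdim,
                               int stride, int pt, int pb, int pl, int pr,
                               int Hin, int Win, NumericVector bias,
                               NumericVector act_y = NumericVector(0),
                               int act = 0, double slope = 0.0) {
  const int Ho = ydim[0], Wo = ydim[1], Cout = ydim[2], N = ydim[3];
  const int K = wdim[0], C = wdim[2];
  const int HoWo = Ho * Wo, KKC = K * K * C;
  arma::fvec dyf = as_fvec(dy);
  arma::fmat Wm(as_fvec(w).memptr(), KKC, Cout);

  arma::fvec dxf((size_t)Hin * Win * C * N, arma::fill::zeros);
  if (bias.size()) {   // transposed-convolution use: seed output with bias
    const size_t HW = (size_t)Hin * Win;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        float* p = dxf.memptr() + HW * (c + (size_t)C * n);
        std::fill(p, p + HW, (float)bias[c]);
      }
  }
  const int nc0 = chunk_size(N, HoWo, KKC);
  arma::fmat dY(HoWo * nc0, Cout);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    const int nc = std::min(nc0, N - n0);
    if (nc != nc0) dY.set_size(HoWo * nc, Cout);
    for (int co = 0; co < Cout; ++co) {
      float* dst = dY.colptr(co);
      for (int nl = 0; nl < nc; ++nl) {
        const float* src =
            dyf.memptr() + (size_t)HoWo * (co + (size_t)Cout * (n0 + nl));
        std::copy(src, src + HoWo, dst + (size_t)HoWo * nl);
      }
    }
    arma::fmat dcol = dY * Wm.t();                    // (HoWo*nc) x KKC
    col2im(dcol, dxf.memptr(), Hin, Win, C, n0, nc, K, stride, pt, pl, Ho, Wo);
  }
  NumericVector dx((R_xlen_t)Hin * Win * C * N);
  if (act == 1 && act_y.size()) {       // chain through a preceding lrelu
    const double* yp = REAL(act_y);
    const float sl = (float)slope;
    for (R_xlen_t i = 0; i < dx.size(); ++i)
      dx[i] = yp[i] > 0 ? (double)dxf[i] : (double)(sl * dxf[i]);
  } else if (act == 2 && act_y.size()) {  // preceding tanh
    const double* yp = REAL(act_y);
    for (R_xlen_t i = 0; i < dx.size(); ++i)
      dx[i] = (double)dxf[i] * (1.0 - yp[i] * yp[i]);
  } else {
    for (R_xlen_t i = 0; i < dx.size(); ++i) dx[i] = (double)dxf[i];
  }
  dx.attr("dim") = IntegerVector::create(Hin, Win, C, N);
  return dx;
}

// Combined transposed-convolution backward: one im2col of the incoming
// gradient feeds both the input gradient (a convolution of dy by w) and
// the weight gradient (correlation with the cached input), plus the bias
// gradient, in a single pass.
// [[Rcpp::export]]
List cpp_tconv_bw(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector wdim,
                  NumericVector dy, IntegerVector ydim,
                  int stride, int pt, int pb, int pl, int pr) {
  const int Hy = ydim[0], Wy = ydim[1], Cy = ydim[2], N = ydim[3];
  const int K = wdim[0], Co = wdim[2], Ci = wdim[3];
  const int Hi = xdim[0], Wi = xdim[1];
  if (Cy != Co) stop("gradient channels do not match filter");
  // adjoint convolution: dy (output space) -> input space (Hi, Wi, Ci)
  const int Ho = (Hy + pt + pb - K) / stride + 1;
  const int Wo = (Wy + pl + pr - K) / stride + 1;
  if (Ho != Hi || Wo != Wi) stop("shape mismatch in transposed backward");
  const int HoWo = Ho * Wo, KKC = K * K * Co;
  arma::fvec dyf = as_fvec(dy);
  arma::fvec xf = as_fvec(x);
  arma::fmat Wm(as_fvec(w).memptr(), KKC, Ci);

  NumericVector dx((R_xlen_t)Hi * Wi * Ci * N);
  arma::fmat dW(KKC, Ci, arma::fill::zeros);
  NumericVector db(Co);
  // bias gradient: channel sums of dy
  {
    const size_t HW = (size_t)Hy * Wy;
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Co; ++c) {
        const float* p = dyf.memptr() + HW * (c + (size_t)Co * n);
        double s = 0.0;
        for (size_t i = 0; i < HW; ++i) s += p[i];
        db[c] += s;
      }
  }
  const int nc0 = chunk_size(N, HoWo, KKC);
  arma::fmat col(HoWo * nc0, KKC);
  arma::fmat Xm(HoWo * nc0, Ci);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    const int nc = std::min(nc0, N - n0);
    if (nc != nc0) { col.set_size(HoWo * nc, KKC); Xm.set_size(HoWo * nc, Ci); }
    im2col(dyf.memptr(), Hy, Wy, Co, n0, nc, K, stride, pt, pl, Ho, Wo, col);
    for (int ci = 0; ci < Ci; ++ci) {
      float* dst = Xm.colptr(ci);
      for (int nl = 0; nl < nc; ++nl) {
        const float* src =
            xf.memptr() + (size_t)HoWo * (ci + (size_t)Ci * (n0 + nl));
        std::copy(src, src + HoWo, dst + (size_t)HoWo * nl);
      }
    }
    dW += col.t() * Xm;
    arma::fmat Y = col * Wm;                 // (HoWo*nc) x Ci: input grads
    for (int ci = 0; ci < Ci; ++ci) {
      const float* src = Y.colptr(ci);
      for (int nl = 0; nl < nc; ++nl) {
        double* dst =
            REAL(dx) + (size_t)HoWo * (ci + (size_t)Ci * (n0 + nl));
        const float* s = src + (size_t)HoWo * nl;
        for (int i = 0; i < HoWo; ++i) dst[i] = (double)s[i];
      }
    }
  }
  dx.attr("dim") = xdim;
  NumericVector dwv((R_xlen_t)KKC * Ci);
  for (R_xlen_t i = 0; i < dwv.size(); ++i) dwv[i] = (double)dW.memptr()[i];
  dwv.attr("dim") = IntegerVector::create(K, K, Co, Ci);
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_conv_bw_filter(NumericVector x, IntegerVector xdim,
                        NumericVector dy, IntegerVector ydim,
                        int K, int stride, int pt, int pb, int pl, int pr) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = ydim[0], Wo = ydim[1], Cout = ydim[2];
  const int HoWo = Ho * Wo, KKC = K * K * C;
  arma::fvec xf = as_fvec(x);
  arma::fvec dyf = as_fvec(dy);

  arma::fmat dW(KKC, Cout, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  const int nc0 = chunk_size(N, HoWo, KKC);
  arma::fmat col(HoWo * nc0, KKC);
  arma::fmat dY(HoWo * nc0, Cout);
  for (int n0 = 0; n0 < N; n0 += nc0) {
    const int nc = std::min(nc0, N - n0);
    if (nc != nc0) { col.set_size(HoWo * nc, KKC); dY.set_size(HoWo * nc, Cout); }
    im2col(xf.memptr(), H, W, C, n0, nc, K, stride, pt, pl, Ho, Wo, col);
    for (int co = 0; co < Cout; ++co) {
      float* dst = dY.colptr(co);
      for (int nl = 0; nl < nc; ++nl) {
        const float* src =
            dyf.memptr() + (size_t)HoWo * (co + (size_t)Cout * (n0 + nl));
        std::copy(src, src + HoWo, dst + (size_t)HoWo * nl);
      }
    }
    dW += col.t() * dY;
    db += arma::sum(dY, 0).t();
  }
  NumericVector dw((R_xlen_t)KKC * Cout);
  for (R_xlen_t i = 0; i < dw.size(); ++i) dw[i] = (double)dW.memptr()[i];
  dw.attr("dim") = IntegerVector::create(K, K, C, Cout);
  NumericVector dbv(Cout);
  for (int i = 0; i < Cout; ++i) dbv[i] = (double)db[i];
  return List::create(_["dw"] = dw, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim,
                    int K, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);   // flat index into x
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; size_t bi = 0;
          for (int kw = 0; kw < K; ++kw) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int hi = ho * stride + kh - pad;
              if (hi < 0 || hi >= H) continue;
              const double v = xs[hi + (size_t)H * wi];
              if (v > best) { best = v; bi = base + hi + (size_t)H * wi; }
            }
          }
          // column-major output: ho fastest, but we iterate wo outer; index directly
          const R_xlen_t oo = o + ho + (R_xlen_t)Ho * wo;
          yp[oo] = best;
          ip[oo] = (int)bi;
        }
      o += (R_xlen_t)Ho * Wo;
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx,
                             IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  double* dxp = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ip[i]] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Plane-accumulation transposed convolution for small kernels
// (K*K*Cin*Cout small): per output channel a single cached plane is
// accumulated over input channels and kernel shifts, avoiding the im2col
// buffers that dominate when the arithmetic intensity is low. Weight layout
// (K, K, Cout, Cin) matches the package's transposed-convolution layers.
// Output size Ho = (Hi - 1) * stride + K - pt - pb (square images).
// [[Rcpp::export]]
NumericVector cpp_tconv_small_fw(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias, int stride,
                                 int pt, int pl, int out_size,
                                 int act = 0, double slope = 0.0) {
  const int Hi = xdim[0], Wi = xdim[1], Ci = xdim[2], N = xdim[3];
  const int K = wdim[0], Co = wdim[2];
  const int Ho = out_size, Wo = out_size;
  arma::fvec xf = as_fvec(x);
  arma::fvec wf = as_fvec(w);
  NumericVector y((R_xlen_t)Ho * Wo * Co * N);
  arma::fvec plane((size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      plane.fill(bias.size() ? (float)bias[co] : 0.0f);
      for (int ci = 0; ci < Ci; ++ci) {
        const float* xp = xf.memptr() + (size_t)Hi * Wi * (ci + (size_t)Ci * n);
        for (int kw = 0; kw < K; ++kw)
          for (int kh = 0; kh < K; ++kh) {
            const float wv =
                wf[(size_t)kh + K * kw + (size_t)K * K * (co + (size_t)Co * ci)];
            for (int wi = 0; wi < Wi; ++wi) {
              const int wo = wi * stride + kw - pl;
              if (wo < 0 || wo >= Wo) continue;
              const float* xc = xp + (size_t)Hi * wi;
              float* oc = plane.memptr() + (size_t)Ho * wo + (kh - pt);
              int hlo = 0, hhi = Hi;
              if (kh - pt < 0) hlo = (pt - kh + stride - 1) / stride;
              while (hhi > hlo && (hhi - 1) * stride + kh - pt >= Ho) --hhi;
              for (int hi = hlo; hi < hhi; ++hi)
                oc[(size_t)hi * stride] += wv * xc[hi];
            }
          }
      }
      double* dst = REAL(y) + (size_t)Ho * Wo * (co + (size_t)Co * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i)
        dst[i] = (double)apply_act(plane[i], act, (float)slope);
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// (leaky) ReLU without R-level temporaries; slope 0 gives plain ReLU
// [[Rcpp::export]]
NumericVector cpp_lrelu_fw(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bw(NumericVector x, NumericVector dy, double slope) {
  NumericVector dx(dy.size());
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dxp[i] = xp[i] > 0 ? dyp[i] : slope * dyp[i];
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// One fused Adam update: returns new parameter and moment vectors computed
// in a single pass (the R fallback needs ~8 full-vector passes).
// [[Rcpp::export]]
List cpp_adam_step(NumericVector par, NumericVector grad,
                   NumericVector m, NumericVector v,
                   double lr, double beta1, double beta2, double eps,
                   double c1, double c2) {
  R_xlen_t n = par.size();
  NumericVector p2(n), m2(n), v2(n);
  const double* pp = REAL(par); const double* gp = REAL(grad);
  const double* mp = m.size() ? REAL(m) : nullptr;
  const double* vp = v.size() ? REAL(v) : nullptr;
  double* po = REAL(p2); double* mo = REAL(m2); double* vo = REAL(v2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = gp[i];
    const double mi = beta1 * (mp ? mp[i] : 0.0) + (1.0 - beta1) * g;
    const double vi = beta2 * (vp ? vp[i] : 0.0) + (1.0 - beta2) * g * g;
    mo[i] = mi; vo[i] = vi;
    po[i] = pp[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  p2.attr("dim") = par.attr("dim");
  return List::create(_["par"] = p2, _["m"] = m2, _["v"] = v2);
}

// Batch normalization over channel axis of (H, W, C, N) arrays, with an
// optionally fused activation on the output.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, IntegerVector xdim,
               NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar,
               double eps, double momentum, bool training,
               int act = 0, double slope = 0.0) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector y(x.size());
  NumericVector mean(C), var(C), nrmean(C), nrvar(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    double mu, v2;
    if (training) {
      double s = 0.0, ss = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xs = xp + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) { s += xs[i]; ss += xs[i] * xs[i]; }
      }
      mu = s / m;
      v2 = ss / m - mu * mu;
      if (v2 < 0) v2 = 0;
      nrmean[c] = (1.0 - momentum) * rmean[c] + momentum * mu;
      nrvar[c]  = (1.0 - momentum) * rvar[c]  + momentum * v2;
    } else {
      mu = rmean[c];
      v2 = rvar[c];
      nrmean[c] = rmean[c];
      nrvar[c] = rvar[c];
    }
    mean[c] = mu; var[c] = v2;
    const float inv = (float)(1.0 / std::sqrt(v2 + eps));
    const float g = (float)gamma[c], b = (float)beta[c], mf = (float)mu;
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + HW * (c + (size_t)C * n);
      double* ys = yp + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i)
        ys[i] = (double)apply_act(g * (((float)xs[i] - mf) * inv) + b,
                                  act, (float)slope);
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, NumericVector dy, IntegerVector xdim,
               NumericVector gamma, NumericVector mean, NumericVector var,
               double eps,
               NumericVector act_y = NumericVector(0),
               int act = 0, double slope = 0.0) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  const double* ayp = act_y.size() ? REAL(act_y) : nullptr;
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* xs = xp + off;
      const double* ds = dyp + off;
      const double* ay = ayp ? ayp + off : nullptr;
      for (size_t i = 0; i < HW; ++i) {
        double d = ds[i];
        if (act == 1 && ay) d = ay[i] > 0 ? d : slope * d;
        const double xh = (xs[i] - mean[c]) * inv;
        sdy += d;
        sdyx += d * xh;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const float k1 = (float)(sdy / m), k2 = (float)(sdyx / m);
    const float gi = (float)(gamma[c] * inv), mf = (float)mean[c],
                invf = (float)inv;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* xs = xp + off;
      const double* ds = dyp + off;
      const double* ay = ayp ? ayp + off : nullptr;
      double* os = dxp + off;
      for (size_t i = 0; i < HW; ++i) {
        float d = (float)ds[i];
        if (act == 1 && ay) d = ay[i] > 0 ? d : (float)slope * d;
        const float xh = ((float)xs[i] - mf) * invf;
        os[i] = (double)(gi * (d - k1 - xh * k2));
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
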