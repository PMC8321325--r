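// Low-level tensor kernels for the convolutional engine.
//
// Tensor layout everywhere: column-major R array with dim (H, W, C, N),
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights: dim (kh, kw, Cin, Cout).
//
// Convolutions are computed as one batch-stacked im2col (patch matrix K of
// size N*Ho*Wo x kh*kw*Cin) followed by a single BLAS GEMM; the forward
// pass can hand K back as an external pointer so the backward pass reuses
// it instead of rebuilding. All kernels are deterministic.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

static NumericVector alloc4(int a, int b, int c, int d, bool init = false) {
  NumericVector v = init ? NumericVector((R_xlen_t)a * b * c * d)
                         : NumericVector(no_init((R_xlen_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Fill rows [n*HoWo, (n+1)*HoWo) of the stacked patch matrix K for sample
// n; reads and writes are contiguous in the fast (h) index.
static void im2col_block(const double* x, int H, int W, int C, long n_off,
                         int kh, int kw, int stride, int pad, int dil,
                         int Ho, int Wo, double* Kp, long ldK, long row_off) {
  const long HoWo = (long)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + n_off + (long)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        long r = ki + (long)kh * (kj + (long)kw * c);
        double* kcol = Kp + ldK * r + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          double* kc = kcol + (long)Ho * wo;
          int w = wo * stride - pad + kj * dil;
          if (w < 0 || w >= W) {
            memset(kc, 0, Ho * sizeof(double));
            continue;
          }
          const double* col = xc + (long)w * H;
          int ho0 = 0, ho1 = Ho;
          while (ho0 < Ho && ho0 * stride - pad + ki * dil < 0) ++ho0;
          while (ho1 > ho0 && (ho1 - 1) * stride - pad + ki * dil >= H) --ho1;
          if (ho0 > 0) memset(kc, 0, ho0 * sizeof(double));
          if (ho1 < Ho) memset(kc + ho1, 0, (Ho - ho1) * sizeof(double));
          if (stride == 1) {
            memcpy(kc + ho0, col + (long)ho0 - pad + ki * dil,
                   (ho1 - ho0) * sizeof(double));
          } else {
            for (int ho = ho0; ho < ho1; ++ho)
              kc[ho] = col[(long)ho * stride - pad + ki * dil];
          }
        }
      }
    }
  }
}

// Scatter-add rows [n*HoWo, (n+1)*HoWo) of the stacked patch gradient back
// onto sample n's input grid.
static void col2im_block(const double* GKp, long ldK, long row_off,
                         double* gx, int H, int W, int C, long n_off,
                         int kh, int kw, int stride, int pad, int dil,
                         int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + n_off + (long)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        long r = ki + (long)kh * (kj + (long)kw * c);
        const double* kcol = GKp + ldK * r + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + kj * dil;
          if (w < 0 || w >= W) continue;
          double* col = gxc + (long)w * H;
          const double* kc = kcol + (long)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + ki * dil;
            if (h < 0 || h >= H) continue;
            col[h] += kc[ho];
          }
        }
      }
    }
  }
}


// Reusable buffer pool for cached patch matrices: training repeats the
// same allocation sizes every step, so buffers are recycled instead of
// returned to the OS (avoids page-fault churn on large fresh mmaps).
struct KBuf { size_t n; double* p; };
static std::vector<KBuf> k_pool;
static double* pool_get(size_t n) {
  for (size_t i = 0; i < k_pool.size(); ++i)
    if (k_pool[i].n == n) {
      double* p = k_pool[i].p;
      k_pool.erase(k_pool.begin() + i);
      return p;
    }
  return (double*)malloc(n * sizeof(double));
}
static void kbuf_finalizer(KBuf* b) {
  if (k_pool.size() >= 128) free(b->p);
  else k_pool.push_back(*b);
  delete b;
}
typedef XPtr<KBuf, PreserveStorage, kbuf_finalizer> KBufPtr;

// [[Rcpp::export(name = ".conv2d_fw")]]
List conv2d_fw(NumericVector x, NumericVector w, NumericVector bias,
               int stride, int pad, int dil, bool ret_k) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weight expects %d", C, Cin);
  int Ho = out_size(H, kh, stride, pad, dil);
  int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  long HoWo = (long)Ho * Wo;
  long R = (long)kh * kw * Cin;

  bool unit = (kh == 1 && kw == 1 && stride == 1 && pad == 0 && dil == 1);
  if (unit) {
    arma::mat Wm(w.begin(), R, Cout, false, true);
    NumericVector y = alloc4(Ho, Wo, Cout, N);
    for (int n = 0; n < N; ++n) {
      arma::mat Xv(const_cast<double*>(x.begin()) + (long)n * HoWo * C,
                   HoWo, C, false, true);
      arma::mat Y(y.begin() + (long)n * HoWo * Cout, HoWo, Cout, false, true);
      Y = Xv * Wm;
      if (bias.size() == Cout)
        for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
    }
    return List::create(_["y"] = y, _["K"] = R_NilValue);
  }

  // patch matrices: one per sample, stored side by side when cached
  KBuf* kb = nullptr;
  if (ret_k) kb = new KBuf{(size_t)(HoWo * R * N), pool_get(HoWo * R * N)};
  arma::mat Kloc;
  if (!ret_k) Kloc.set_size(HoWo, R);
  arma::mat Wm(w.begin(), R, Cout, false, true);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  bool has_bias = bias.size() == Cout;

  for (int n = 0; n < N; ++n) {
    double* Kp = ret_k ? kb->p + (long)n * HoWo * R : Kloc.memptr();
    im2col_block(x.begin(), H, W, C, (long)n * H * W * C, kh, kw, stride,
                 pad, dil, Ho, Wo, Kp, HoWo, 0);
    arma::mat Kv(Kp, HoWo, R, false, true);
    arma::mat Y(y.begin() + (long)n * HoWo * Cout, HoWo, Cout, false, true);
    Y = Kv * Wm;
    if (has_bias)
      for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  }
  if (ret_k) {
    KBufPtr kp(kb, true);
    return List::create(_["y"] = y, _["K"] = kp);
  }
  return List::create(_["y"] = y, _["K"] = R_NilValue);
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad, int dil, bool has_bias, bool need_gx,
               SEXP kcache) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  long HoWo = (long)Ho * Wo;
  long R = (long)kh * kw * Cin;

  bool unit = (kh == 1 && kw == 1 && stride == 1 && pad == 0 && dil == 1);
  if (unit) {
    NumericVector gw = alloc4(1, 1, Cin, Cout, true);
    arma::mat GW(gw.begin(), Cin, Cout, false, true);
    arma::mat Wm(w.begin(), Cin, Cout, false, true);
    NumericVector gx = need_gx ? alloc4(H, W, C, N) : NumericVector(0);
    NumericVector gb(has_bias ? Cout : 0);
    for (int n = 0; n < N; ++n) {
      arma::mat GY(gy.begin() + (long)n * HoWo * Cout, HoWo, Cout, false, true);
      arma::mat Xv(const_cast<double*>(x.begin()) + (long)n * HoWo * Cin,
                   HoWo, Cin, false, true);
      GW += Xv.t() * GY;
      if (need_gx) {
        arma::mat GX(gx.begin() + (long)n * HoWo * Cin, HoWo, Cin, false, true);
        GX = GY * Wm.t();
      }
      if (has_bias)
        for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(GY.col(co));
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  KBuf* kb = nullptr;
  if (kcache != R_NilValue) kb = KBufPtr(kcache).get();
  arma::mat Kloc;
  if (!kb) Kloc.set_size(HoWo, R);

  NumericVector gw = alloc4(kh, kw, Cin, Cout, true);
  arma::mat GW(gw.begin(), R, Cout, false, true);
  arma::mat Wm(w.begin(), R, Cout, false, true);
  NumericVector gx = need_gx ? alloc4(H, W, C, N, true) : NumericVector(0);
  NumericVector gb(has_bias ? Cout : 0);

  for (int n = 0; n < N; ++n) {
    arma::mat GY(gy.begin() + (long)n * HoWo * Cout, HoWo, Cout, false, true);
    double* Kp;
    if (kb) {
      Kp = kb->p + (long)n * HoWo * R;
    } else {
      Kp = Kloc.memptr();
      im2col_block(x.begin(), H, W, C, (long)n * H * W * C, kh, kw, stride,
                   pad, dil, Ho, Wo, Kp, HoWo, 0);
    }
    arma::mat Kv(Kp, HoWo, R, false, true);
    GW += Kv.t() * GY;
    if (need_gx) {
      arma::mat GK = GY * Wm.t();  // (HoWo x R)
      col2im_block(GK.memptr(), HoWo, 0, gx.begin(), H, W, C,
                   (long)n * H * W * C, kh, kw, stride, pad, dil, Ho, Wo);
    }
    if (has_bias)
      for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(GY.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector x, NumericVector g) {
  NumericVector gx(no_init(x.size()));
  gx.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? gp[i] : 0;
  return gx;
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  NumericVector y = alloc4(Ho, Wo, C, N);
  NumericVector idx = alloc4(Ho, Wo, C, N);  // 0-based argmax into x
  const double* xp = x.begin();
  double* yp = y.begin();
  double* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long base = ((long)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; long bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            int w = wo * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              long pos = base + (long)w * H + h;
              if (xp[pos] > best) { best = xp[pos]; bi = pos; }
            }
          }
          long oo = ((long)n * C + c) * Ho * Wo + (long)wo * Ho + ho;
          yp[oo] = best; ip[oo] = (double)bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector idx, NumericVector gy,
                         IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3], true);
  const double* ip = idx.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) {
    long pos = (long)ip[i];
    if (pos >= 0) gxp[pos] += gp[i];
  }
  return gx;
}

// Adaptive average pooling onto an oh x ow grid of near-equal cells.
// [[Rcpp::export(name = ".avgpool_adaptive_fw")]]
NumericVector avgpool_adaptive_fw(NumericVector x, int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = alloc4(oh, ow, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long base = ((long)n * C + c) * H * W;
      long obase = ((long)n * C + c) * oh * ow;
      for (int j = 0; j < ow; ++j) {
        int w0 = (int)std::floor((double)j * W / ow);
        int w1 = (int)std::ceil((double)(j + 1) * W / ow);
        for (int i = 0; i < oh; ++i) {
          int h0 = (int)std::floor((double)i * H / oh);
          int h1 = (int)std::ceil((double)(i + 1) * H / oh);
          double s = 0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) s += xp[base + (long)w * H + h];
          yp[obase + (long)j * oh + i] = s / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".avgpool_adaptive_bw")]]
NumericVector avgpool_adaptive_bw(NumericVector gy, IntegerVector xdim) {
  IntegerVector gd = gy.attr("dim");
  int oh = gd[0], ow = gd[1];
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx = alloc4(H, W, C, N, true);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long base = ((long)n * C + c) * H * W;
      long obase = ((long)n * C + c) * oh * ow;
      for (int j = 0; j < ow; ++j) {
        int w0 = (int)std::floor((double)j * W / ow);
        int w1 = (int)std::ceil((double)(j + 1) * W / ow);
        for (int i = 0; i < oh; ++i) {
          int h0 = (int)std::floor((double)i * H / oh);
          int h1 = (int)std::ceil((double)(i + 1) * H / oh);
          double g = gp[obase + (long)j * oh + i] / ((h1 - h0) * (w1 - w0));
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) gxp[base + (long)w * H + h] += g;
        }
      }
    }
  return gx;
}

// Bilinear resize with half-pixel centre alignment (source coordinate of
// output pixel i is (i + 0.5) * H/oh - 0.5, clamped to the frame).
static inline void lin_coef(int o, int in, int osz, int& i0, int& i1,
                            double& t) {
  double s = ((double)o + 0.5) * in / osz - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = i0 < in - 1 ? i0 + 1 : i0;
  t = s - i0;
}

// [[Rcpp::export(name = ".resize_bilinear_fw")]]
NumericVector resize_bilinear_fw(NumericVector x, int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = alloc4(oh, ow, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<double> th(oh), tw(ow);
  for (int i = 0; i < oh; ++i) lin_coef(i, H, oh, h0[i], h1[i], th[i]);
  for (int j = 0; j < ow; ++j) lin_coef(j, W, ow, w0[j], w1[j], tw[j]);
  long planes = (long)C * N;
  for (long p = 0; p < planes; ++p) {
    const double* xpl = xp + p * H * W;
    double* ypl = yp + p * (long)oh * ow;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double a = xpl[(long)w0[j] * H + h0[i]];
        double b = xpl[(long)w0[j] * H + h1[i]];
        double c = xpl[(long)w1[j] * H + h0[i]];
        double d = xpl[(long)w1[j] * H + h1[i]];
        double left = a + (b - a) * th[i], right = c + (d - c) * th[i];
        ypl[(long)j * oh + i] = left + (right - left) * tw[j];
      }
  }
  return y;
}

// [[Rcpp::export(name = ".resize_bilinear_bw")]]
NumericVector resize_bilinear_bw(NumericVector gy, IntegerVector xdim) {
  IntegerVector gd = gy.attr("dim");
  int oh = gd[0], ow = gd[1];
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx = alloc4(H, W, C, N, true);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  std::vector<int> h0(oh), h1(oh), w0(ow), w1(ow);
  std::vector<double> th(oh), tw(ow);
  for (int i = 0; i < oh; ++i) lin_coef(i, H, oh, h0[i], h1[i], th[i]);
  for (int j = 0; j < ow; ++j) lin_coef(j, W, ow, w0[j], w1[j], tw[j]);
  long planes = (long)C * N;
  for (long p = 0; p < planes; ++p) {
    const double* gpl = gp + p * (long)oh * ow;
    double* gxpl = gxp + p * H * W;
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double g = gpl[(long)j * oh + i];
        gxpl[(long)w0[j] * H + h0[i]] += g * (1 - th[i]) * (1 - tw[j]);
        gxpl[(long)w0[j] * H + h1[i]] += g * th[i] * (1 - tw[j]);
        gxpl[(long)w1[j] * H + h0[i]] += g * (1 - th[i]) * tw[j];
        gxpl[(long)w1[j] * H + h1[i]] += g * th[i] * tw[j];
      }
  }
  return gx;
}

// ---- batch normalisation helpers (per-channel statistics over H, W, N) ----

// [[Rcpp::export(name = ".bn_moments")]]
List bn_moments(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  long HW = (long)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + ((long)n * C + c) * HW;
      for (long i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (HW * N);
    double v = s2 / (HW * N) - m * m;
    mean[c] = m; var[c] = v < 0 ? 0 : v;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = xhat * gamma[c] + beta[c] with xhat = (x - mean[c]) * istd[c]
// [[Rcpp::export(name = ".bn_norm")]]
List bn_norm(NumericVector x, NumericVector mean, NumericVector istd,
             NumericVector gamma, NumericVector beta, bool keep_xhat) {
  IntegerVector xd = x.attr("dim");
  long HW = (long)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  NumericVector y = alloc4(xd[0], xd[1], C, N);
  NumericVector xhat = keep_xhat ? alloc4(xd[0], xd[1], C, N)
                                 : NumericVector(0);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = keep_xhat ? xhat.begin() : (double*)nullptr;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      long off = ((long)n * C + c) * HW;
      double m = mean[c], is = istd[c], g = gamma[c], b = beta[c];
      for (long i = 0; i < HW; ++i) {
        double xh = (xp[off + i] - m) * is;
        if (hp) hp[off + i] = xh;
        yp[off + i] = xh * g + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// backward; training mode uses the batch-statistic chain rule
// gx = gamma*istd * (gy - mean(gy) - xhat * mean(gy * xhat))
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector xhat, NumericVector gy, NumericVector gamma,
           NumericVector istd, bool training) {
  IntegerVector xd = gy.attr("dim");
  long HW = (long)xd[0] * xd[1];
  int C = xd[2], N = xd[3];
  long M = HW * N;
  NumericVector gx = alloc4(xd[0], xd[1], C, N);
  NumericVector ggamma(C), gbeta(C);
  const double* gp = gy.begin();
  const double* hp = xhat.size() ? xhat.begin() : (double*)nullptr;
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgh = 0;
    for (int n = 0; n < N; ++n) {
      long off = ((long)n * C + c) * HW;
      for (long i = 0; i < HW; ++i) {
        sg += gp[off + i];
        if (hp) sgh += gp[off + i] * hp[off + i];
      }
    }
    gbeta[c] = sg; ggamma[c] = sgh;
    double k = gamma[c] * istd[c];
    double mg = sg / M, mgh = sgh / M;
    for (int n = 0; n < N; ++n) {
      long off = ((long)n * C + c) * HW;
      if (training && hp)
        for (long i = 0; i < HW; ++i)
          op[off + i] = k * (gp[off + i] - mg - hp[off + i] * mgh);
      else
        for (long i = 0; i < HW; ++i) op[off + i] = k * gp[off + i];
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}
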