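// Low-level numeric kernels for the network engine.
//
// Array convention throughout: feature maps are dense double arrays with
// dim = (H, W, C, N), column-major as in R. Convolution weights are
// (kh, kw, C_in, C_out); stride is always 1 except the 2x2 stride-2
// transposed convolution used by the decoder.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int dim_i(const NumericVector& x, int k) {
  IntegerVector d = x.attr("dim");
  return d[k];
}

// im2col: rows indexed by (ho + Ho*wo + Ho*Wo*n), cols by (i + kh*(j + kw*c)).
static void im2col(const double* x, int H, int W, int C, int N,
                   int kh, int kw, int pad, arma::mat& cols) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const int HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        double* dst = cols.colptr(col);
        for (int n = 0; n < N; ++n) {
          const double* xs = x + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = wo - pad + j;
            double* drow = dst + (size_t)n * HWo + (size_t)Ho * wo;
            if (wsrc < 0 || wsrc >= W) {
              std::fill(drow, drow + Ho, 0.0);
              continue;
            }
            const double* xcolp = xs + (size_t)H * wsrc;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hsrc = ho - pad + i;
              drow[ho] = (hsrc < 0 || hsrc >= H) ? 0.0 : xcolp[hsrc];
            }
          }
        }
      }
    }
  }
}

// scatter-add of a cols-shaped gradient back onto the input grid
static void col2im(const arma::mat& gcols, int H, int W, int C, int N,
                   int kh, int kw, int pad, double* gx) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const int HWo = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        const double* src = gcols.colptr(col);
        for (int n = 0; n < N; ++n) {
          double* gxs = gx + (size_t)H * W * (c + (size_t)C * n);
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = wo - pad + j;
            if (wsrc < 0 || wsrc >= W) continue;
            const double* srow = src + (size_t)n * HWo + (size_t)Ho * wo;
            double* gcolp = gxs + (size_t)H * wsrc;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hsrc = ho - pad + i;
              if (hsrc >= 0 && hsrc < H) gcolp[hsrc] += srow[ho];
            }
          }
        }
      }
    }
  }
}

// forward pass; optionally hands the im2col matrix back for reuse in the
// backward pass
// [[Rcpp::export]]
List cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                   int pad, bool keep_cols) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int kh = dim_i(w, 0), kw = dim_i(w, 1), K = dim_i(w, 3);
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  NumericMatrix colsR((size_t)Ho * Wo * N, (size_t)kh * kw * C);
  arma::mat cols(colsR.begin(), colsR.nrow(), colsR.ncol(), false, true);
  im2col(REAL(x), H, W, C, N, kh, kw, pad, cols);
  arma::mat wm(const_cast<double*>(REAL(w)), (size_t)kh * kw * C, K, false, true);
  arma::mat y = cols * wm;
  const double* bp = REAL(b);
  NumericVector out((size_t)Ho * Wo * K * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, K, N);
  double* op = REAL(out);
  const size_t HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      const double* yc = y.colptr(k) + (size_t)n * HWo;
      double* oc = op + HWo * (k + (size_t)K * n);
      const double bk = bp[k];
      for (size_t t = 0; t < HWo; ++t) oc[t] = yc[t] + bk;
    }
  if (keep_cols) return List::create(_["y"] = out, _["cols"] = colsR);
  return List::create(_["y"] = out);
}

// backward pass reusing the forward im2col matrix; gx computed only when
// the input needs a gradient
// [[Rcpp::export]]
List cpp_conv2d_bw(NumericMatrix colsR, NumericVector w, NumericVector gy,
                   int pad, int H, int W, bool need_gx) {
  const int kh = dim_i(w, 0), kw = dim_i(w, 1), C = dim_i(w, 2),
            K = dim_i(w, 3);
  const int Ho = dim_i(gy, 0), Wo = dim_i(gy, 1);
  const int N = dim_i(gy, 3);
  const size_t HWo = (size_t)Ho * Wo;
  // reshape gy to (Ho*Wo*N) x K
  arma::mat gym(HWo * N, K);
  const double* gp = REAL(gy);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      const double* src = gp + HWo * (k + (size_t)K * n);
      std::copy(src, src + HWo, gym.colptr(k) + (size_t)n * HWo);
    }
  arma::mat cols(colsR.begin(), colsR.nrow(), colsR.ncol(), false, true);
  arma::mat gw = cols.t() * gym;                       // (kh*kw*C) x K
  NumericVector gwv(gw.memptr(), gw.memptr() + gw.n_elem);
  gwv.attr("dim") = IntegerVector::create(kh, kw, C, K);
  arma::rowvec gb = arma::sum(gym, 0);
  NumericVector gbv(gb.begin(), gb.end());
  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gwv, _["gb"] = gbv);
  arma::mat wm(const_cast<double*>(REAL(w)), (size_t)kh * kw * C, K, false, true);
  arma::mat gcols = gym * wm.t();                      // rows x (kh*kw*C)
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im(gcols, H, W, C, N, kh, kw, pad, REAL(gx));
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// 2x2 stride-2 transposed convolution: out(2i+a, 2j+b, k) += x(i,j,c)*w(a,b,c,k)
// [[Rcpp::export]]
NumericVector cpp_upconv2_fw(NumericVector x, NumericVector w,
                             NumericVector b) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int K = dim_i(w, 3);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * K * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, K, N);
  double* op = REAL(out);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      double* oc = op + (size_t)Ho * Wo * (k + (size_t)K * n);
      const double bk = bp[k];
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) oc[t] = bk;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
        const double* wk = wp + 4 * (c + (size_t)C * k);   // (a,b) block
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xc[i + (size_t)H * j];
            double* o00 = oc + (2 * i) + (size_t)Ho * (2 * j);
            o00[0]      += v * wk[0];        // a=0,b=0
            o00[1]      += v * wk[1];        // a=1,b=0
            o00[Ho]     += v * wk[2];        // a=0,b=1
            o00[Ho + 1] += v * wk[3];        // a=1,b=1
          }
      }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_upconv2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int K = dim_i(w, 3);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((size_t)4 * C * K);
  gw.attr("dim") = IntegerVector::create(2, 2, C, K);
  NumericVector gb(K);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  double* gbp = REAL(gb);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      const double* gc = gp + (size_t)Ho * Wo * (k + (size_t)K * n);
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) gbp[k] += gc[t];
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
        double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
        const double* wk = wp + 4 * (c + (size_t)C * k);
        double* gwk = gwp + 4 * (c + (size_t)C * k);
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xc[i + (size_t)H * j];
            const double* g00 = gc + (2 * i) + (size_t)Ho * (2 * j);
            gxc[i + (size_t)H * j] += g00[0] * wk[0] + g00[1] * wk[1] +
                                      g00[Ho] * wk[2] + g00[Ho + 1] * wk[3];
            gwk[0] += v * g00[0];
            gwk[1] += v * g00[1];
            gwk[2] += v * g00[Ho];
            gwk[3] += v * g00[Ho + 1];
          }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++t) {
          const double* base = xc + (2 * ho) + (size_t)H * (2 * wo);
          double best = base[0];
          int arg = 0;
          if (base[1] > best)     { best = base[1];     arg = 1; }
          if (base[H] > best)     { best = base[H];     arg = 2; }
          if (base[H + 1] > best) { best = base[H + 1]; arg = 3; }
          yp[t] = best;
          ip[t] = arg;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector gy,
                              int H, int W) {
  const int Ho = dim_i(gy, 0), Wo = dim_i(gy, 1);
  const int C = dim_i(gy, 2), N = dim_i(gy, 3);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  const int* ip = INTEGER(idx);
  double* gxp = REAL(gx);
  size_t t = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++t) {
          const int arg = ip[t];
          const int dh = arg & 1, dw = arg >> 1;
          gxc[(2 * ho + dh) + (size_t)H * (2 * wo + dw)] += gp[t];
        }
    }
  return gx;
}

// depth-wise 'valid' correlation of every channel with one fixed kernel
// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, NumericMatrix k) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int kh = k.nrow(), kw = k.ncol();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  const double* kp = REAL(k);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* yc = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double* ycol = yc + (size_t)Ho * wo;
        std::fill(ycol, ycol + Ho, 0.0);
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double kv = kp[i + kh * j];
            const double* xcol = xc + i + (size_t)H * (wo + j);
            for (int ho = 0; ho < Ho; ++ho) ycol[ho] += kv * xcol[ho];
          }
      }
    }
  return y;
}

// separable 'valid' correlation: rows pass with kcol, then columns pass
// with krow (for rank-1 kernels k = kcol %o% krow)
// [[Rcpp::export]]
NumericVector cpp_dwconv_sep_fw(NumericVector x, NumericVector kcol,
                                NumericVector krow) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int kh = kcol.size(), kw = krow.size();
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  const double* xp = REAL(x);
  const double* kc = REAL(kcol);
  const double* kr = REAL(krow);
  std::vector<double> tmp((size_t)Ho * W);  // per (c, n) plane
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* yc = yp + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w) {
        double* t = tmp.data() + (size_t)Ho * w;
        const double* xcol = xc + (size_t)H * w;
        std::fill(t, t + Ho, 0.0);
        for (int i = 0; i < kh; ++i) {
          const double kv = kc[i];
          for (int ho = 0; ho < Ho; ++ho) t[ho] += kv * xcol[ho + i];
        }
      }
      for (int wo = 0; wo < Wo; ++wo) {
        double* ycol = yc + (size_t)Ho * wo;
        std::fill(ycol, ycol + Ho, 0.0);
        for (int j = 0; j < kw; ++j) {
          const double kv = kr[j];
          const double* t = tmp.data() + (size_t)Ho * (wo + j);
          for (int ho = 0; ho < Ho; ++ho) ycol[ho] += kv * t[ho];
        }
      }
    }
  return y;
}

// gradient of the separable correlation w.r.t. x: scatter gy through the
// column pass, then through the row pass
// [[Rcpp::export]]
NumericVector cpp_dwconv_sep_bw(NumericVector kcol, NumericVector krow,
                                NumericVector gy, int H, int W) {
  const int Ho = dim_i(gy, 0), Wo = dim_i(gy, 1);
  const int C = dim_i(gy, 2), N = dim_i(gy, 3);
  const int kh = kcol.size(), kw = krow.size();
  const double* gp = REAL(gy);
  const double* kc = REAL(kcol);
  const double* kr = REAL(krow);
  std::vector<double> tmp((size_t)Ho * W);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* gcol = gc + (size_t)Ho * wo;
        for (int j = 0; j < kw; ++j) {
          const double kv = kr[j];
          double* t = tmp.data() + (size_t)Ho * (wo + j);
          for (int ho = 0; ho < Ho; ++ho) t[ho] += kv * gcol[ho];
        }
      }
      for (int w = 0; w < W; ++w) {
        const double* t = tmp.data() + (size_t)Ho * w;
        double* gcol = gxc + (size_t)H * w;
        for (int i = 0; i < kh; ++i) {
          const double kv = kc[i];
          for (int ho = 0; ho < Ho; ++ho) gcol[ho + i] += kv * t[ho];
        }
      }
    }
  return gx;
}

// gradient of cpp_dwconv_fw w.r.t. x (scatter of gy through the kernel)
// [[Rcpp::export]]
NumericVector cpp_dwconv_bw(NumericMatrix k, NumericVector gy, int H, int W) {
  const int Ho = dim_i(gy, 0), Wo = dim_i(gy, 1);
  const int C = dim_i(gy, 2), N = dim_i(gy, 3);
  const int kh = k.nrow(), kw = k.ncol();
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  const double* kp = REAL(k);
  double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* gcol = gc + (size_t)Ho * wo;
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const double kv = kp[i + kh * j];
            double* xcol = gxc + i + (size_t)H * (wo + j);
            for (int ho = 0; ho < Ho; ++ho) xcol[ho] += kv * gcol[ho];
          }
      }
    }
  return gx;
}

// reflect-101 padding (mirror without repeating the edge pixel)
// [[Rcpp::export]]
NumericVector cpp_pad_reflect_fw(NumericVector x, int p) {
  const int H = dim_i(x, 0), W = dim_i(x, 1), C = dim_i(x, 2), N = dim_i(x, 3);
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<int> mh(Hp), mw(Wp);
  for (int i = 0; i < Hp; ++i) {
    int s = i - p;
    if (s < 0) s = -s;
    if (s >= H) s = 2 * (H - 1) - s;
    mh[i] = s;
  }
  for (int j = 0; j < Wp; ++j) {
    int s = j - p;
    if (s < 0) s = -s;
    if (s >= W) s = 2 * (W - 1) - s;
    mw[j] = s;
  }
  NumericVector y((size_t)Hp * Wp * C * N);
  y.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* yc = yp + (size_t)Hp * Wp * (c + (size_t)C * n);
      for (int j = 0; j < Wp; ++j)
        for (int i = 0; i < Hp; ++i)
          yc[i + (size_t)Hp * j] = xc[mh[i] + (size_t)H * mw[j]];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_pad_reflect_bw(NumericVector gy, int p, int H, int W) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const int C = dim_i(gy, 2), N = dim_i(gy, 3);
  std::vector<int> mh(Hp), mw(Wp);
  for (int i = 0; i < Hp; ++i) {
    int s = i - p;
    if (s < 0) s = -s;
    if (s >= H) s = 2 * (H - 1) - s;
    mh[i] = s;
  }
  for (int j = 0; j < Wp; ++j) {
    int s = j - p;
    if (s < 0) s = -s;
    if (s >= W) s = 2 * (W - 1) - s;
    mw[j] = s;
  }
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + (size_t)Hp * Wp * (c + (size_t)C * n);
      double* gxc = gxp + (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < Wp; ++j)
        for (int i = 0; i < Hp; ++i)
          gxc[mh[i] + (size_t)H * mw[j]] += gc[i + (size_t)Hp * j];
    }
  return gx;
}
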