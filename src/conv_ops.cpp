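// Convolution kernels for the keypoint networks.
//
// Tensor layout everywhere: R arrays dim c(H, W, C, N), column-major, so a
// single (channel, sample) plane is contiguous and H runs fastest.
// Convolution weights: dim c(kh, kw, in_per_group, out_channels).
// Transposed-convolution weights: dim c(kh, kw, out_per_group, in_channels).
// All heavy lifting is im2col + GEMM (Armadillo / BLAS); depthwise
// convolutions fall out of the grouped path with one-column GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Gather one (sample, group) into a (kh*kw*ipg) x (oH*oW) matrix.
static void im2col(const double* x, int H, int W, int ipg, int c0,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int oH, int oW, arma::mat& col) {
  for (int ci = 0; ci < ipg; ++ci) {
    const double* plane = x + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int oj = 0; oj < oW; ++oj) {
          int w = oj * sw - pw + kj;
          double* dst = col.colptr(oH * oj) + r; // stride col.n_rows between cols
          if (w < 0 || w >= W) {
            for (int oi = 0; oi < oH; ++oi) dst[(size_t)oi * col.n_rows] = 0.0;
            continue;
          }
          const double* src = plane + (size_t)w * H;
          for (int oi = 0; oi < oH; ++oi) {
            int h = oi * sh - ph + ki;
            dst[(size_t)oi * col.n_rows] = (h >= 0 && h < H) ? src[h] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the transpose operation of im2col.
static void col2im_add(const arma::mat& col, double* x, int H, int W, int ipg,
                       int c0, int kh, int kw, int sh, int sw, int ph, int pw,
                       int oH, int oW) {
  for (int ci = 0; ci < ipg; ++ci) {
    double* plane = x + (size_t)(c0 + ci) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int oj = 0; oj < oW; ++oj) {
          int w = oj * sw - pw + kj;
          if (w < 0 || w >= W) continue;
          const double* src = col.colptr(oH * oj) + r;
          double* dstp = plane + (size_t)w * H;
          for (int oi = 0; oi < oH; ++oi) {
            int h = oi * sh - ph + ki;
            if (h >= 0 && h < H) dstp[h] += src[(size_t)oi * col.n_rows];
          }
        }
      }
    }
  }
}


// Direct depthwise convolution (groups == C, one in/out channel per group).
static void dw_fwd(const double* x, const double* w, int H, int W, int C,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int oH, int oW, double* y) {
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    const double* wc = w + (size_t)c * kh * kw;
    double* yc = y + (size_t)c * oH * oW;
    for (int oj = 0; oj < oW; ++oj)
      for (int oi = 0; oi < oH; ++oi) {
        double acc = 0;
        int h0 = oi * sh - ph, w0 = oj * sw - pw;
        for (int kj = 0; kj < kw; ++kj) {
          int wv = w0 + kj;
          if (wv < 0 || wv >= W) continue;
          const double* colp = plane + (size_t)wv * H;
          const double* wcol = wc + kj * kh;
          for (int ki = 0; ki < kh; ++ki) {
            int hv = h0 + ki;
            if (hv >= 0 && hv < H) acc += wcol[ki] * colp[hv];
          }
        }
        yc[oi + (size_t)oj * oH] = acc;
      }
  }
}

static void dw_bwd(const double* x, const double* w, const double* gy,
                   int H, int W, int C, int kh, int kw, int sh, int sw,
                   int ph, int pw, int oH, int oW, double* gx, double* gw) {
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    const double* wc = w + (size_t)c * kh * kw;
    const double* gyc = gy + (size_t)c * oH * oW;
    double* gxc = gx + (size_t)c * H * W;
    double* gwc = gw + (size_t)c * kh * kw;
    for (int oj = 0; oj < oW; ++oj)
      for (int oi = 0; oi < oH; ++oi) {
        double g = gyc[oi + (size_t)oj * oH];
        if (g == 0) continue;
        int h0 = oi * sh - ph, w0 = oj * sw - pw;
        for (int kj = 0; kj < kw; ++kj) {
          int wv = w0 + kj;
          if (wv < 0 || wv >= W) continue;
          const double* colp = plane + (size_t)wv * H;
          double* gcolp = gxc + (size_t)wv * H;
          for (int ki = 0; ki < kh; ++ki) {
            int hv = h0 + ki;
            if (hv >= 0 && hv < H) {
              gcolp[hv] += wc[kj * kh + ki] * g;
              gwc[kj * kh + ki] += colp[hv] * g;
            }
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, IntegerVector xdim,
                             int kh, int kw, int sh, int sw, int ph, int pw,
                             int groups, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int outC = w.size() / (kh * kw * (C / groups));
  int ipg = C / groups, opg = outC / groups;
  int oH = conv_out(H, kh, sh, ph), oW = conv_out(W, kw, sw, pw);
  NumericVector y(no_init((size_t)oH * oW * outC * N));
  y.attr("dim") = IntegerVector::create(oH, oW, outC, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  bool one_by_one = (kh == 1 && kw == 1 && sh == 1 && sw == 1 &&
                     ph == 0 && pw == 0 && groups == 1);
  bool depthwise = (groups == C && ipg == 1 && opg == 1);
  if (one_by_one) {
    arma::mat Wm(const_cast<double*>(w.begin()), C, outC, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(xp) + (size_t)n * H * W * C,
                  (size_t)H * W, C, false, true);
      arma::mat Y(yp + (size_t)n * (size_t)oH * oW * outC,
                  (size_t)oH * oW, outC, false, true);
      Y = X * Wm;
      if (has_bias)
        for (int j = 0; j < outC; ++j) Y.col(j) += bias[j];
    }
    return y;
  }
  if (depthwise) {
    for (int n = 0; n < N; ++n) {
      dw_fwd(xp + (size_t)n * H * W * C, w.begin(), H, W, C, kh, kw, sh, sw,
             ph, pw, oH, oW, yp + (size_t)n * (size_t)oH * oW * outC);
      if (has_bias)
        for (int c = 0; c < outC; ++c) {
          double* pl = yp + (size_t)oH * oW * (c + (size_t)n * outC);
          for (size_t i = 0; i < (size_t)oH * oW; ++i) pl[i] += bias[c];
        }
    }
    return y;
  }
  arma::mat col(kh * kw * ipg, oH * oW);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, ipg, g * ipg, kh, kw, sh, sw, ph, pw, oH, oW, col);
      arma::mat Wm(const_cast<double*>(w.begin()) +
                       (size_t)(kh * kw * ipg) * g * opg,
                   kh * kw * ipg, opg, false, true);
      arma::mat Y(yp + (size_t)oH * oW * (g * opg + (size_t)n * outC),
                  oH * oW, opg, false, true);
      Y = col.t() * Wm;
      if (has_bias)
        for (int j = 0; j < opg; ++j) Y.col(j) += bias[g * opg + j];
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector xdim, int kh, int kw, int sh, int sw,
                    int ph, int pw, int groups, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int ipg = C / groups;
  int outC = w.size() / (kh * kw * ipg);
  int opg = outC / groups;
  int oH = conv_out(H, kh, sh, ph), oW = conv_out(W, kw, sw, pw);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  NumericVector gw(w.size());
  gw.attr("dim") = IntegerVector::create(kh, kw, ipg, outC);
  NumericVector gb(outC);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  bool one_by_one = (kh == 1 && kw == 1 && sh == 1 && sw == 1 &&
                     ph == 0 && pw == 0 && groups == 1);
  bool depthwise = (groups == C && ipg == 1 && opg == 1);
  if (one_by_one) {
    arma::mat Wm(const_cast<double*>(w.begin()), C, outC, false, true);
    arma::mat GWm(gw.begin(), C, outC, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(xp) + (size_t)n * H * W * C,
                  (size_t)H * W, C, false, true);
      arma::mat G(const_cast<double*>(gyp) + (size_t)n * (size_t)oH * oW * outC,
                  (size_t)oH * oW, outC, false, true);
      arma::mat GX(gx.begin() + (size_t)n * H * W * C,
                   (size_t)H * W, C, false, true);
      GX = G * Wm.t();
      GWm += X.t() * G;
      if (has_bias)
        for (int j = 0; j < outC; ++j) gb[j] += arma::accu(G.col(j));
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  if (depthwise) {
    for (int n = 0; n < N; ++n) {
      dw_bwd(xp + (size_t)n * H * W * C, w.begin(),
             gyp + (size_t)n * (size_t)oH * oW * outC, H, W, C, kh, kw,
             sh, sw, ph, pw, oH, oW, gx.begin() + (size_t)n * H * W * C,
             gw.begin());
      if (has_bias)
        for (int c = 0; c < outC; ++c) {
          const double* pl = gyp + (size_t)oH * oW * (c + (size_t)n * outC);
          double s2 = 0;
          for (size_t i = 0; i < (size_t)oH * oW; ++i) s2 += pl[i];
          gb[c] += s2;
        }
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat col(kh * kw * ipg, oH * oW);
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * C;
    double* gxn = gx.begin() + (size_t)n * H * W * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, ipg, g * ipg, kh, kw, sh, sw, ph, pw, oH, oW, col);
      arma::mat Wm(const_cast<double*>(w.begin()) +
                       (size_t)(kh * kw * ipg) * g * opg,
                   kh * kw * ipg, opg, false, true);
      arma::mat G(const_cast<double*>(gyp) +
                      (size_t)oH * oW * (g * opg + (size_t)n * outC),
                  oH * oW, opg, false, true);
      arma::mat GW(gw.begin() + (size_t)(kh * kw * ipg) * g * opg,
                   kh * kw * ipg, opg, false, true);
      GW += col * G;
      arma::mat gcol = Wm * G.t();
      col2im_add(gcol, gxn, H, W, ipg, g * ipg, kh, kw, sh, sw, ph, pw, oH, oW);
      if (has_bias)
        for (int j = 0; j < opg; ++j) gb[g * opg + j] += arma::accu(G.col(j));
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution: forward is the data-gradient of a conv whose
// "output" is x; weights are dim c(kh, kw, out_per_group, in_channels).

// [[Rcpp::export]]
NumericVector convt2d_fwd_cpp(NumericVector x, NumericVector w,
                              NumericVector bias, IntegerVector xdim,
                              int kh, int kw, int sh, int sw, int ph, int pw,
                              int groups, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int ipg = C / groups;
  int opg = w.size() / (kh * kw * C);
  int outC = opg * groups;
  int oH = (H - 1) * sh + kh - 2 * ph, oW = (W - 1) * sw + kw - 2 * pw;
  NumericVector y((size_t)oH * oW * outC * N);
  y.attr("dim") = IntegerVector::create(oH, oW, outC, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    double* yn = y.begin() + (size_t)n * oH * oW * outC;
    for (int g = 0; g < groups; ++g) {
      arma::mat X(const_cast<double*>(xp) +
                      (size_t)H * W * (g * ipg + (size_t)n * C),
                  H * W, ipg, false, true);
      arma::mat Wm(const_cast<double*>(w.begin()) +
                       (size_t)(kh * kw * opg) * g * ipg,
                   kh * kw * opg, ipg, false, true);
      arma::mat gcol = Wm * X.t();
      col2im_add(gcol, yn, oH, oW, opg, g * opg, kh, kw, sh, sw, ph, pw, H, W);
    }
    if (has_bias)
      for (int c = 0; c < outC; ++c) {
        double* plane = yn + (size_t)c * oH * oW;
        for (size_t i = 0; i < (size_t)oH * oW; ++i) plane[i] += bias[c];
      }
  }
  return y;
}

// [[Rcpp::export]]
List convt2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                     IntegerVector xdim, int kh, int kw, int sh, int sw,
                     int ph, int pw, int groups, bool has_bias) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int ipg = C / groups;
  int opg = w.size() / (kh * kw * C);
  int outC = opg * groups;
  int oH = (H - 1) * sh + kh - 2 * ph, oW = (W - 1) * sw + kw - 2 * pw;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  NumericVector gw(w.size());
  gw.attr("dim") = IntegerVector::create(kh, kw, opg, C);
  NumericVector gb(outC);
  arma::mat col(kh * kw * opg, H * W);
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (size_t)n * oH * oW * outC;
    for (int g = 0; g < groups; ++g) {
      im2col(gyn, oH, oW, opg, g * opg, kh, kw, sh, sw, ph, pw, H, W, col);
      arma::mat Wm(const_cast<double*>(w.begin()) +
                       (size_t)(kh * kw * opg) * g * ipg,
                   kh * kw * opg, ipg, false, true);
      arma::mat GX(gx.begin() + (size_t)H * W * (g * ipg + (size_t)n * C),
                   H * W, ipg, false, true);
      GX = col.t() * Wm;
      arma::mat X(const_cast<double*>(x.begin()) +
                      (size_t)H * W * (g * ipg + (size_t)n * C),
                  H * W, ipg, false, true);
      arma::mat GW(gw.begin() + (size_t)(kh * kw * opg) * g * ipg,
                   kh * kw * opg, ipg, false, true);
      GW += col * X;
    }
    if (has_bias)
      for (int c = 0; c < outC; ++c) {
        const double* plane = gyn + (size_t)c * oH * oW;
        double s = 0.0;
        for (size_t i = 0; i < (size_t)oH * oW; ++i) s += plane[i];
        gb[c] += s;
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, IntegerVector xdim, int k, int s,
                       int p) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int oH = (H + 2 * p - k) / s + 1, oW = (W + 2 * p - k) / s + 1;
  NumericVector y(no_init((size_t)oH * oW * C * N));
  y.attr("dim") = IntegerVector::create(oH, oW, C, N);
  IntegerVector idx(no_init((size_t)oH * oW * C * N)); // 1-based linear index into x
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)H * W * (c + (size_t)n * C);
      size_t base = (size_t)H * W * (c + (size_t)n * C);
      for (int oj = 0; oj < oW; ++oj)
        for (int oi = 0; oi < oH; ++oi) {
          double best = -1e300;
          size_t bi = 0;
          bool found = false;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki) {
              int h = oi * s - p + ki, w2 = oj * s - p + kj;
              if (h < 0 || h >= H || w2 < 0 || w2 >= W) continue;
              double v = plane[h + (size_t)w2 * H];
              if (!found || v > best) {
                best = v; bi = base + h + (size_t)w2 * H; found = true;
              }
            }
          size_t oo = (size_t)oi + (size_t)oH * (oj + (size_t)oW * (c + (size_t)n * C));
          y[oo] = best;
          idx[oo] = (int)(bi + 1);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector gy, IntegerVector idx,
                                IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// Batch norm over (H, W, N) per channel. Planes for a given (channel,
// sample) are contiguous, so statistics are accumulated plane-wise.

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, IntegerVector xdim, NumericVector gamma,
                NumericVector beta, NumericVector rm, NumericVector rv,
                double eps, double momentum, bool training) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t hw = (size_t)H * W;
  NumericVector y(no_init(x.size()));
  y.attr("dim") = xdim;
  NumericVector xhat(no_init(x.size()));
  NumericVector invstd(C), new_rm(clone(rm)), new_rv(clone(rv));
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + hw * (c + (size_t)n * C);
        for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      new_rm[c] = (1 - momentum) * rm[c] + momentum * m;
      new_rv[c] = (1 - momentum) * rv[c] +
        momentum * v * M / (M > 1 ? M - 1 : 1);
    } else {
      m = rm[c];
      v = rv[c];
    }
    double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)n * C);
      const double* p = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yp = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        double z = (p[i] - m) * is;
        xh[i] = z;
        yp[i] = g * z + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rm"] = new_rm, _["rv"] = new_rv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector g, NumericVector xhat, IntegerVector xdim,
                NumericVector invstd, NumericVector gamma, bool training) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t hw = (size_t)H * W;
  NumericVector gx(no_init(g.size()));
  gx.attr("dim") = xdim;
  NumericVector ggamma(C), gbeta(C);
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)n * C);
      const double* gp = g.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t i = 0; i < hw; ++i) { sg += gp[i]; sgx += gp[i] * xh[i]; }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    double gm = gamma[c], is = invstd[c];
    double t1 = sg / M, t2 = sgx / M;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)n * C);
      const double* gp = g.begin() + off;
      const double* xh = xhat.begin() + off;
      double* gxp = gx.begin() + off;
      if (training)
        for (size_t i = 0; i < hw; ++i)
          gxp[i] = gm * is * (gp[i] - t1 - xh[i] * t2);
      else
        for (size_t i = 0; i < hw; ++i) gxp[i] = gm * is * gp[i];
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x, double cap) {
  NumericVector y(no_init(x.size()));
  const double* xp = x.begin();
  double* yp = y.begin();
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = xp[i];
    yp[i] = v < 0 ? 0 : (v > cap ? cap : v);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector g, NumericVector x, double cap) {
  NumericVector gx(no_init(g.size()));
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* op = gx.begin();
  R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i)
    op[i] = (xp[i] <= 0 || xp[i] >= cap) ? 0 : gp[i];
  return gx;
}

// ---- fused conv/convT + batch norm + activation ----------------------------
//
// The separate conv -> BN -> ReLU layers are memory-bound on this class of
// hardware; fusing the normalization and activation into the convolution
// call removes several full-tensor passes and two R-level allocations per
// block. act: 0 = identity, 1 = ReLU capped at `cap`.

static void bn_act_fwd(NumericVector& conv_out, IntegerVector ydim,
                       NumericVector gamma, NumericVector beta,
                       NumericVector rm, NumericVector rv, double eps,
                       double momentum, bool training, int act, double cap,
                       NumericVector& out, NumericVector& invstd,
                       NumericVector& new_rm, NumericVector& new_rv) {
  int H = ydim[0], W = ydim[1], C = ydim[2], N = ydim[3];
  size_t hw = (size_t)H * W;
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = conv_out.begin() + hw * (c + (size_t)n * C);
        for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      new_rm[c] = (1 - momentum) * rm[c] + momentum * m;
      new_rv[c] = (1 - momentum) * rv[c] +
        momentum * v * M / (M > 1 ? M - 1 : 1);
    } else {
      m = rm[c];
      v = rv[c];
    }
    double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    double gg = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)n * C);
      double* xh = conv_out.begin() + off; // becomes xhat in place
      double* op = out.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        double z = (xh[i] - m) * is;
        xh[i] = z;
        double o = gg * z + bb;
        if (act == 1) o = o < 0 ? 0 : (o > cap ? cap : o);
        op[i] = o;
      }
    }
  }
}

// Masked BN backward: turns the post-activation gradient into the gradient
// at the convolution output (written into gz), accumulating the affine
// parameter gradients.
static void bn_act_bwd(NumericVector g, NumericVector y, NumericVector xhat,
                       IntegerVector ydim, NumericVector invstd,
                       NumericVector gamma, bool training, int act,
                       double cap, NumericVector& gz, NumericVector& ggamma,
                       NumericVector& gbeta) {
  int H = ydim[0], W = ydim[1], C = ydim[2], N = ydim[3];
  size_t hw = (size_t)H * W;
  double M = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)n * C);
      const double* gp = g.begin() + off;
      const double* yp = y.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        double gm = gp[i];
        if (act == 1 && (yp[i] <= 0 || yp[i] >= cap)) gm = 0;
        sg += gm;
        sgx += gm * xh[i];
      }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    double is = invstd[c], gc = gamma[c];
    double t1 = sg / M, t2 = sgx / M;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)n * C);
      const double* gp = g.begin() + off;
      const double* yp = y.begin() + off;
      const double* xh = xhat.begin() + off;
      double* gzp = gz.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        double gm = gp[i];
        if (act == 1 && (yp[i] <= 0 || yp[i] >= cap)) gm = 0;
        gzp[i] = training ? gc * is * (gm - t1 - xh[i] * t2)
                          : gc * is * gm;
      }
    }
  }
}

// [[Rcpp::export]]
List fused_cbr_fwd_cpp(NumericVector x, NumericVector w, IntegerVector xdim,
                       int k, int s, int p, int groups, NumericVector gamma,
                       NumericVector beta, NumericVector rm, NumericVector rv,
                       double eps, double momentum, bool training, int act,
                       double cap) {
  NumericVector conv_out = conv2d_fwd_cpp(x, w, 0.0, xdim, k, k, s, s, p, p,
                                          groups, false);
  IntegerVector ydim = conv_out.attr("dim");
  int C = ydim[2];
  NumericVector out(no_init(conv_out.size()));
  out.attr("dim") = ydim;
  NumericVector invstd(C), new_rm(clone(rm)), new_rv(clone(rv));
  bn_act_fwd(conv_out, ydim, gamma, beta, rm, rv, eps, momentum, training,
             act, cap, out, invstd, new_rm, new_rv);
  return List::create(_["y"] = out, _["xhat"] = conv_out,
                      _["invstd"] = invstd, _["rm"] = new_rm,
                      _["rv"] = new_rv);
}

// [[Rcpp::export]]
List fused_cbr_bwd_cpp(NumericVector g, NumericVector y, NumericVector xhat,
                       NumericVector invstd, NumericVector gamma,
                       NumericVector x, NumericVector w, IntegerVector xdim,
                       int k, int s, int p, int groups, bool training,
                       int act, double cap) {
  IntegerVector ydim = g.attr("dim");
  int C = ydim[2];
  NumericVector gz(no_init(g.size()));
  gz.attr("dim") = ydim;
  NumericVector ggamma(C), gbeta(C);
  bn_act_bwd(g, y, xhat, ydim, invstd, gamma, training, act, cap, gz,
             ggamma, gbeta);
  List r = conv2d_bwd_cpp(x, w, gz, xdim, k, k, s, s, p, p, groups, false);
  return List::create(_["gx"] = r["gx"], _["gw"] = r["gw"],
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
List fused_tbr_fwd_cpp(NumericVector x, NumericVector w, IntegerVector xdim,
                       int k, int s, int p, int groups, NumericVector gamma,
                       NumericVector beta, NumericVector rm, NumericVector rv,
                       double eps, double momentum, bool training, int act,
                       double cap) {
  NumericVector conv_out = convt2d_fwd_cpp(x, w, 0.0, xdim, k, k, s, s, p, p,
                                           groups, false);
  IntegerVector ydim = conv_out.attr("dim");
  int C = ydim[2];
  NumericVector out(no_init(conv_out.size()));
  out.attr("dim") = ydim;
  NumericVector invstd(C), new_rm(clone(rm)), new_rv(clone(rv));
  bn_act_fwd(conv_out, ydim, gamma, beta, rm, rv, eps, momentum, training,
             act, cap, out, invstd, new_rm, new_rv);
  return List::create(_["y"] = out, _["xhat"] = conv_out,
                      _["invstd"] = invstd, _["rm"] = new_rm,
                      _["rv"] = new_rv);
}

// [[Rcpp::export]]
List fused_tbr_bwd_cpp(NumericVector g, NumericVector y, NumericVector xhat,
                       NumericVector invstd, NumericVector gamma,
                       NumericVector x, NumericVector w, IntegerVector xdim,
                       int k, int s, int p, int groups, bool training,
                       int act, double cap) {
  IntegerVector ydim = g.attr("dim");
  int C = ydim[2];
  NumericVector gz(no_init(g.size()));
  gz.attr("dim") = ydim;
  NumericVector ggamma(C), gbeta(C);
  bn_act_bwd(g, y, xhat, ydim, invstd, gamma, training, act, cap, gz,
             ggamma, gbeta);
  List r = convt2d_bwd_cpp(x, w, gz, xdim, k, k, s, s, p, p, groups, false);
  return List::create(_["gx"] = r["gx"], _["gw"] = r["gw"],
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
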