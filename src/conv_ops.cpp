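// Low-level tensor kernels for the segmentation network.
// Layout convention throughout: feature maps are numeric arrays with
// dim = c(H, W, C, N) (column-major, H fastest). Convolution weights are
// passed as a (k*k*Cin) x Cout matrix whose row order matches the
// column-major flattening of an array with dim = c(k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(arma::uword i, arma::uword j, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return i + H * (j + W * (c + C * n));
}

// im2col for same-padded k x k convolution (k odd), one sample.
// col is (H*W) x (k*k*C); column q = di + k*dj + k*k*c (0-based).
static void im2col(const double* x, arma::mat& col, int H, int W, int C,
                   int k) {
  int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int q = di + k * dj + k * k * c;
        double* dst = col.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) dst[i + H * j] = 0.0;
            continue;
          }
          const double* src = x + (arma::uword)H * (sj + (arma::uword)W * c);
          for (int i = 0; i < H; ++i) {
            int si = i + di - pad;
            dst[i + H * j] = (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im_add(const arma::mat& col, double* gx, int H, int W,
                       int C, int k) {
  int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int q = di + k * dj + k * k * c;
        const double* src = col.colptr(q);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          double* dst = gx + (arma::uword)H * (sj + (arma::uword)W * c);
          for (int i = 0; i < H; ++i) {
            int si = i + di - pad;
            if (si >= 0 && si < H) dst[si] += src[i + H * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix wmat,
                           NumericVector b, int k) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Co = wmat.ncol();
  if (wmat.nrow() != k * k * C) stop("weight/input channel mismatch");
  NumericVector y((R_xlen_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat Wm(wmat.begin(), wmat.nrow(), Co, false);
  arma::rowvec bv(b.begin(), Co);
  arma::mat col(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (arma::uword)H * W * C * n, col, H, W, C, k);
    arma::mat Y = col * Wm;
    Y.each_row() += bv;
    std::copy(Y.memptr(), Y.memptr() + (arma::uword)H * W * Co,
              y.begin() + (arma::uword)H * W * Co * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix wmat, NumericVector gy,
                  int k) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Co = wmat.ncol();
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = d;
  arma::mat Wm(wmat.begin(), wmat.nrow(), Co, false);
  arma::mat gW(k * k * C, Co, arma::fill::zeros);
  arma::rowvec gb(Co, arma::fill::zeros);
  arma::mat col(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (arma::uword)H * W * C * n, col, H, W, C, k);
    arma::mat gY(const_cast<double*>(gy.begin()) + (arma::uword)H * W * Co * n,
                 H * W, Co, false);
    gW += col.t() * gY;
    gb += arma::sum(gY, 0);
    arma::mat gcol = gY * Wm.t();
    col2im_add(gcol, gx.begin() + (arma::uword)H * W * C * n, H, W, C, k);
  }
  NumericMatrix gWout(k * k * C, Co);
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gWout.begin());
  NumericVector gbout(Co);
  std::copy(gb.memptr(), gb.memptr() + Co, gbout.begin());
  return List::create(_["gx"] = gx, _["gw"] = gWout, _["gb"] = gbout);
}

// 2x2 max pooling, stride 2. Returns pooled map and 0-based argmax offsets
// into the input array (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int H2 = H / 2, W2 = W / 2;
  NumericVector y((R_xlen_t)H2 * W2 * C * N);
  IntegerVector idx((R_xlen_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  R_xlen_t p = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          double best = R_NegInf;
          arma::uword besto = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              arma::uword o = idx4(2 * i + di, 2 * j + dj, c, n, H, W, C);
              if (x[o] > best) {
                best = x[o];
                besto = o;
              }
            }
          y[p] = best;
          idx[p] = (int)besto;
          ++p;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy, int H,
                               int W) {
  IntegerVector d = gy.attr("dim");
  int C = d[2], N = d[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t p = 0; p < gy.size(); ++p) gx[idx[p]] += gy[p];
  return gx;
}

// 2x2 stride-2 transposed convolution. w has dim c(2, 2, Cin, Cout),
// passed flattened; output pixel (2i+di, 2j+dj) gets sum_ci x[i,j,ci] *
// w[di,dj,ci,co] + b[co].
// [[Rcpp::export]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w,
                              NumericVector b) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  IntegerVector dw = w.attr("dim");
  int Co = dw[3];
  NumericVector y((R_xlen_t)4 * H * W * Co * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Co, N);
  std::fill(y.begin(), y.end(), 0.0);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (arma::uword)H * W * Ci * n,
                 H * W, Ci, false);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Wdd(Ci, Co);
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            Wdd(ci, co) = w[di + 2 * (dj + 2 * (ci + (arma::uword)Ci * co))];
        arma::mat Y = Xn * Wdd;  // (H*W) x Co
        for (int co = 0; co < Co; ++co) {
          const double* src = Y.colptr(co);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              arma::uword o = idx4(2 * i + di, 2 * j + dj, co, n, 2 * H,
                                   2 * W, Co);
              // each output pixel has a unique (di,dj) parity, so the bias
              // is added exactly once per pixel
              y[o] += src[i + H * j] + b[co];
            }
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  IntegerVector dw = w.attr("dim");
  int Co = dw[3];
  NumericVector gx((R_xlen_t)H * W * Ci * N);
  gx.attr("dim") = d;
  NumericVector gw(w.size());
  gw.attr("dim") = dw;
  NumericVector gb(Co);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn(const_cast<double*>(x.begin()) + (arma::uword)H * W * Ci * n,
                 H * W, Ci, false);
    arma::mat gXn(gx.begin() + (arma::uword)H * W * Ci * n, H * W, Ci, false,
                  true);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Wdd(Ci, Co), gYdd(H * W, Co);
        for (int co = 0; co < Co; ++co) {
          double* dst = gYdd.colptr(co);
          double acc = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              double g = gy[idx4(2 * i + di, 2 * j + dj, co, n, 2 * H, 2 * W,
                                 Co)];
              dst[i + H * j] = g;
              acc += g;
            }
          gb[co] += acc;
          for (int ci = 0; ci < Ci; ++ci)
            Wdd(ci, co) = w[di + 2 * (dj + 2 * (ci + (arma::uword)Ci * co))];
        }
        gXn += gYdd * Wdd.t();
        arma::mat gWdd = Xn.t() * gYdd;
        for (int co = 0; co < Co; ++co)
          for (int ci = 0; ci < Ci; ++ci)
            gw[di + 2 * (dj + 2 * (ci + (arma::uword)Ci * co))] += gWdd(ci, co);
      }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Crop per-patch windows from a single-channel plane: rows/cols are 1-based
// top-left corners; output dim c(ps, ps, 1, n).
// [[Rcpp::export]]
NumericVector cpp_crop_patches(NumericMatrix plane, IntegerVector rows,
                               IntegerVector cols, int ps) {
  int n = rows.size();
  int H = plane.nrow();
  NumericVector out((R_xlen_t)ps * ps * n);
  out.attr("dim") = IntegerVector::create(ps, ps, 1, n);
  for (int p = 0; p < n; ++p) {
    int r0 = rows[p] - 1, c0 = cols[p] - 1;
    double* dst = out.begin() + (R_xlen_t)ps * ps * p;
    for (int j = 0; j < ps; ++j) {
      const double* src = &plane(r0, c0 + j);
      for (int i = 0; i < ps; ++i) dst[i + ps * j] = src[i];
    }
  }
  return out;
}

// Accumulate overlapping patch predictions back onto a plane (sum and count;
// the mean is taken in R).
// [[Rcpp::export]]
List cpp_accumulate_patches(NumericVector patches, IntegerVector rows,
                            IntegerVector cols, int H, int W) {
  IntegerVector d = patches.attr("dim");
  int ps = d[0];
  int n = d[3];
  NumericMatrix acc(H, W), cnt(H, W);
  for (int p = 0; p < n; ++p) {
    int r0 = rows[p] - 1, c0 = cols[p] - 1;
    const double* src = patches.begin() + (R_xlen_t)ps * ps * p;
    for (int j = 0; j < ps; ++j)
      for (int i = 0; i < ps; ++i) {
        acc(r0 + i, c0 + j) += src[i + ps * j];
        cnt(r0 + i, c0 + j) += 1.0;
      }
  }
  return List::create(_["sum"] = acc, _["count"] = cnt);
}

// ---- fused elementwise / channel kernels (hot path of training) -----------

// per-(channel, sample) sums and sums of squares -> 2 x (C*N) matrix
// [[Rcpp::export]]
NumericMatrix cpp_cn_sums2(NumericVector x) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  int CN = d[2] * d[3];
  NumericMatrix out(2, CN);
  const double* p = x.begin();
  for (int q = 0; q < CN; ++q) {
    double s = 0, ss = 0;
    const double* v = p + hw * q;
    for (R_xlen_t i = 0; i < hw; ++i) {
      s += v[i];
      ss += v[i] * v[i];
    }
    out(0, q) = s;
    out(1, q) = ss;
  }
  return out;
}

// per-(channel, sample) sums of x -> C x N matrix
// [[Rcpp::export]]
NumericMatrix cpp_cn_sums(NumericVector x) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  NumericMatrix out(d[2], d[3]);
  const double* p = x.begin();
  for (int q = 0; q < d[2] * d[3]; ++q) {
    double s = 0;
    const double* v = p + hw * q;
    for (R_xlen_t i = 0; i < hw; ++i) s += v[i];
    out[q] = s;
  }
  return out;
}

// per-(channel, sample) sums of a*b -> C x N matrix
// [[Rcpp::export]]
NumericMatrix cpp_dot_cn(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  NumericMatrix out(d[2], d[3]);
  const double* pa = a.begin();
  const double* pb = b.begin();
  for (int q = 0; q < d[2] * d[3]; ++q) {
    double s = 0;
    const double* va = pa + hw * q;
    const double* vb = pb + hw * q;
    for (R_xlen_t i = 0; i < hw; ++i) s += va[i] * vb[i];
    out[q] = s;
  }
  return out;
}

// y = max(a[c] * x + b[c], 0)  (fused BN affine + ReLU)
// [[Rcpp::export]]
NumericVector cpp_bnrelu_fwd(NumericVector x, NumericVector a,
                             NumericVector b) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* px = x.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double ac = a[c], bc = b[c];
      R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < hw; ++i) {
        double v = ac * px[off + i] + bc;
        py[off + i] = v > 0 ? v : 0;
      }
    }
  return y;
}

// backward of BN (batch statistics) + ReLU in one pass; x is the BN input,
// y the fused output, mu/invsd the batch stats used in the forward pass
// [[Rcpp::export]]
List cpp_bnrelu_bwd(NumericVector gy, NumericVector y, NumericVector x,
                    NumericVector gamma, NumericVector mu,
                    NumericVector invsd, bool training) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  int C = d[2], N = d[3];
  double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  const double* pgy = gy.begin();
  const double* py = y.begin();
  const double* px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      double s1 = 0, s2 = 0;
      for (R_xlen_t i = 0; i < hw; ++i) {
        if (py[off + i] > 0) {
          double g = pgy[off + i];
          s1 += g;
          s2 += g * (px[off + i] - mu[c]) * invsd[c];
        }
      }
      dbeta[c] += s1;
      dgamma[c] += s2;
    }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t off = hw * (c + (R_xlen_t)C * n);
      double gi = gamma[c] * invsd[c];
      if (training) {
        double t1 = dbeta[c] / m, t2 = dgamma[c] / m;
        for (R_xlen_t i = 0; i < hw; ++i) {
          double g = py[off + i] > 0 ? pgy[off + i] : 0.0;
          double xh = (px[off + i] - mu[c]) * invsd[c];
          gx[off + i] = gi * (g - t1 - xh * t2);
        }
      } else {
        for (R_xlen_t i = 0; i < hw; ++i)
          gx[off + i] = py[off + i] > 0 ? gi * pgy[off + i] : 0.0;
      }
    }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// y = x * s[c, n]  (channel gating)
// [[Rcpp::export]]
NumericVector cpp_scale_cn(NumericVector x, NumericMatrix s) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* px = x.begin();
  double* py = y.begin();
  for (int q = 0; q < d[2] * d[3]; ++q) {
    double sc = s[q];
    R_xlen_t off = hw * q;
    for (R_xlen_t i = 0; i < hw; ++i) py[off + i] = px[off + i] * sc;
  }
  return y;
}

// y = x + a[c, n]  (broadcast add)
// [[Rcpp::export]]
NumericVector cpp_add_cn(NumericVector x, NumericMatrix a) {
  IntegerVector d = x.attr("dim");
  R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* px = x.begin();
  double* py = y.begin();
  for (int q = 0; q < d[2] * d[3]; ++q) {
    double ac = a[q];
    R_xlen_t off = hw * q;
    for (R_xlen_t i = 0; i < hw; ++i) py[off + i] = px[off + i] + ac;
  }
  return y;
}

// y = max(a + b, 0)
// [[Rcpp::export]]
NumericVector cpp_add_relu(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const double* pa = a.begin();
  const double* pb = b.begin();
  double* py = y.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    double v = pa[i] + pb[i];
    py[i] = v > 0 ? v : 0;
  }
  return y;
}

// gy * (y > 0)
// [[Rcpp::export]]
NumericVector cpp_mask_mul(NumericVector gy, NumericVector y) {
  NumericVector g(gy.size());
  g.attr("dim") = gy.attr("dim");
  const double* pg = gy.begin();
  const double* py = y.begin();
  double* po = g.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) po[i] = py[i] > 0 ? pg[i] : 0.0;
  return g;
}

// Max-composite Gaussian cross-sections along a sampled curve onto D
// (in place); y/x are 1-based sample coordinates, wid the full width at
// half maximum at each sample.
// [[Rcpp::export]]
void cpp_stamp_curve(NumericMatrix D, NumericVector y, NumericVector x,
                     NumericVector wid) {
  int H = D.nrow(), W = D.ncol();
  for (int p = 0; p < y.size(); ++p) {
    double cy = y[p] - 1.0, cx = x[p] - 1.0;
    double w = wid[p];
    int rad = (int)std::ceil(w) + 1;
    double sig = w / 2.355;
    double inv2s2 = 1.0 / (2.0 * sig * sig);
    int i0 = std::max(0, (int)std::floor(cy) - rad);
    int i1 = std::min(H - 1, (int)std::ceil(cy) + rad);
    int j0 = std::max(0, (int)std::floor(cx) - rad);
    int j1 = std::min(W - 1, (int)std::ceil(cx) + rad);
    for (int j = j0; j <= j1; ++j) {
      double dx2 = (j - cx) * (j - cx);
      for (int i = i0; i <= i1; ++i) {
        double v = std::exp(-((i - cy) * (i - cy) + dx2) * inv2s2);
        if (v > D(i, j)) D(i, j) = v;
      }
    }
  }
}
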