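// Low-level CNN kernels. Tensor layout throughout: column-major R arrays
// with dim (H, W, C, N); convolution weights dim (kh, kw, Cin, Cout).
// Convolutions are im2col + GEMM (Armadillo / BLAS).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column-major col matrix: one column of length kh*kw*C per output pixel,
// filled column-by-column so writes are contiguous and reads over ki walk
// down contiguous input columns.
static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat& col) {
  const int R = kh * kw * C;
  double* cp = col.memptr();
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double* dst = cp + (R_xlen_t)R * (i + (R_xlen_t)Ho * j);
      const int hi0 = i * stride - pad;
      const int wj0 = j * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (R_xlen_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = wj0 + kj;
          double* d = dst + kh * (kj + kw * c);
          if (wj < 0 || wj >= W) {
            for (int ki = 0; ki < kh; ++ki) d[ki] = 0.0;
            continue;
          }
          const double* src = xc + (R_xlen_t)H * wj + hi0;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            d[ki] = (hi >= 0 && hi < H) ? src[ki] : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_add(const arma::mat& col, double* dx, int H, int W, int C,
                              int kh, int kw, int stride, int pad, int Ho, int Wo) {
  const int R = kh * kw * C;
  const double* cp = col.memptr();
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double* src = cp + (R_xlen_t)R * (i + (R_xlen_t)Ho * j);
      const int hi0 = i * stride - pad;
      const int wj0 = j * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (R_xlen_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = wj0 + kj;
          if (wj < 0 || wj >= W) continue;
          const double* s = src + kh * (kj + kw * c);
          double* d = xc + (R_xlen_t)H * wj + hi0;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = hi0 + ki;
            if (hi >= 0 && hi < H) d[ki] += s[ki];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels but weights expect %d", C, wd[2]);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), kh * kw * C, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat col(pointwise ? 1 : kh * kw * C, pointwise ? 1 : (R_xlen_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(y.begin() + (R_xlen_t)n * Ho * Wo * Cout, (R_xlen_t)Ho * Wo, Cout, false, true);
    if (pointwise) {  // input slab (H*W x C) multiplies the weights directly
      arma::mat X(const_cast<double*>(x.begin()) + (R_xlen_t)n * H * W * C,
                  (R_xlen_t)H * W, C, false, true);
      Y = X * Wm;
    } else {
      im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
      Y = col.t() * Wm;
    }
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)kh * kw * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), kh * kw * C, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat col(pointwise ? 1 : kh * kw * C, pointwise ? 1 : (R_xlen_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    arma::mat dY(dy.begin() + (R_xlen_t)n * Ho * Wo * Cout, (R_xlen_t)Ho * Wo, Cout, false, true);
    dbv += arma::sum(dY, 0);
    if (pointwise) {
      arma::mat X(const_cast<double*>(x.begin()) + (R_xlen_t)n * H * W * C,
                  (R_xlen_t)H * W, C, false, true);
      arma::mat dX(dx.begin() + (R_xlen_t)n * H * W * C, (R_xlen_t)H * W, C, false, true);
      dWm += X.t() * dY;
      dX = dY * Wm.t();
    } else {
      im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
      dWm += col * dY;
      arma::mat dcol = Wm * dY.t();
      col2im_add(dcol, dx.begin() + (R_xlen_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batch normalization over (H, W, N) per channel.
// training: batch statistics (returned); else the supplied running statistics.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector running_mean, NumericVector running_var,
            bool training, double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const double M = (double)plane * N;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mean(C), var(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + plane * (c + (R_xlen_t)C * n);
        for (R_xlen_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
    } else {
      m = running_mean[c];
      v = running_var[c];
    }
    mean[c] = m; var[c] = v;
    const double is = 1.0 / std::sqrt(v + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (R_xlen_t)C * n);
      double* q = y.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < plane; ++i) q[i] = g * (p[i] - m) * is + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var, _["invstd"] = invstd);
}

// Backward for training-mode batchnorm (batch statistics).
// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
            NumericVector mean, NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const double M = (double)plane * N;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c], g = gamma[c];
    double s1 = 0.0, s2 = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + plane * (c + (R_xlen_t)C * n);
      const double* pd = dy.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < plane; ++i) {
        const double xh = (px[i] - m) * is;
        s1 += pd[i];
        s2 += pd[i] * xh;
        sb += pd[i];
      }
    }
    dgamma[c] = s2;
    dbeta[c] = sb;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + plane * (c + (R_xlen_t)C * n);
      const double* pd = dy.begin() + plane * (c + (R_xlen_t)C * n);
      double* q = dx.begin() + plane * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < plane; ++i) {
        const double xh = (px[i] - m) * is;
        q[i] = g * is * (pd[i] - (s1 + xh * s2) / M);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Max pooling; padding positions are excluded from the max (never win).
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);  // plane-linear argmax within (H, W)
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = R_NegInf;
          int bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wj = j * stride + kj - pad;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = i * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              const double v = p[hi + (R_xlen_t)H * wj];
              if (v > best) { best = v; bi = hi + H * wj; }
            }
          }
          // output is row-major within column j: position (i, j)
          y[q + i + (R_xlen_t)Ho * j] = best;
          idx[q + i + (R_xlen_t)Ho * j] = bi;
        }
      }
      q += (R_xlen_t)Ho * Wo;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector in_dim) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = in_dim[0], W = in_dim[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  const R_xlen_t iplane = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t ob = oplane * (c + (R_xlen_t)C * n);
      const R_xlen_t ib = iplane * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < oplane; ++i) {
        const int t = idx[ob + i];
        if (t >= 0) dx[ib + t] += dy[ob + i];
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(clone(x));
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx(clone(dy));
  const double* py = y.begin();
  double* p = dx.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (py[i] <= 0) p[i] = 0;
  return dx;
}
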