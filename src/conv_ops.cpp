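// Convolution and pooling kernels for the stream forward/backward passes.
// Feature maps are column-major R arrays with dim (C, H, W, N); weights are
// (C_out, C_in, k, k).  im2col lays patches out so that the flattened weight
// array multiplies them directly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// patches: (C*k*k) x (Ho*Wo*N); row index c + C*(ky + k*kx)
template <typename MatT, typename ElemT>
static void im2col_t(const double* x, int C, int H, int W, int N,
                     int k, int stride, int pad, int Ho, int Wo, MatT& P) {
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        size_t col = (size_t)oy + (size_t)Ho * ox + (size_t)Ho * Wo * n;
        ElemT* pc = P.colptr(col);
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox * stride + kx - pad;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride + ky - pad;
            ElemT* dst = pc + (size_t)C * (ky + k * kx);
            if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
              const double* src = xn + (size_t)C * ((size_t)iy + (size_t)H * ix);
              for (int c = 0; c < C; ++c) dst[c] = (ElemT)src[c];
            } else {
              std::fill(dst, dst + C, (ElemT)0);
            }
          }
        }
      }
    }
  }
}

static void im2col(const double* x, int C, int H, int W, int N,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& P) {
  im2col_t<arma::mat, double>(x, C, H, W, N, k, stride, pad, Ho, Wo, P);
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& Pg, int C, int H, int W, int N,
                   int k, int stride, int pad, int Ho, int Wo, double* dx) {
  for (int n = 0; n < N; ++n) {
    double* xn = dx + (size_t)n * C * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        size_t col = (size_t)oy + (size_t)Ho * ox + (size_t)Ho * Wo * n;
        const double* pc = Pg.colptr(col);
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= H) continue;
            const double* src = pc + (size_t)C * (ky + k * kx);
            double* dst = xn + (size_t)C * ((size_t)iy + (size_t)H * ix);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, int c_out, int k,
                                 NumericVector bias, int stride, int pad) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat P(C * k * k, (size_t)Ho * Wo * N);
  im2col(x.begin(), C, H, W, N, k, stride, pad, Ho, Wo, P);
  arma::mat Wm(w.begin(), c_out, C * k * k, false);
  arma::mat O = Wm * P;
  if (bias.size() == (R_xlen_t)c_out) {
    arma::colvec b(bias.begin(), c_out, false);
    O.each_col() += b;
  }
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(c_out, Ho, Wo, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, int c_out, int k,
                         NumericVector gout, int stride, int pad,
                         bool want_dx) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat P(C * k * k, (size_t)Ho * Wo * N);
  im2col(x.begin(), C, H, W, N, k, stride, pad, Ho, Wo, P);
  arma::mat G(gout.begin(), c_out, (size_t)Ho * Wo * N, false);
  arma::mat Wm(w.begin(), c_out, C * k * k, false);
  arma::mat dW = G * P.t();
  arma::colvec db = arma::sum(G, 1);
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(c_out, C, k, k);
  if (!want_dx) {
    return List::create(_["dx"] = R_NilValue, _["dw"] = dwv,
                        _["db"] = NumericVector(db.begin(), db.end()));
  }
  arma::mat Pg = Wm.t() * G;
  NumericVector dx((R_xlen_t)C * H * W * N);
  col2im(Pg, C, H, W, N, k, stride, pad, Ho, Wo, dx.begin());
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// forward that additionally returns the im2col patch matrix for reuse in
// the backward pass of the same batch
// [[Rcpp::export]]
List cpp_conv2d_forward_patches(NumericVector x, IntegerVector xdim,
                                NumericVector w, int c_out, int k,
                                int stride, int pad) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericMatrix P(C * k * k, (int)((size_t)Ho * Wo * N));
  arma::mat Pm(P.begin(), P.nrow(), P.ncol(), false);
  im2col(x.begin(), C, H, W, N, k, stride, pad, Ho, Wo, Pm);
  arma::mat Wm(w.begin(), c_out, C * k * k, false);
  arma::mat O = Wm * Pm;
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(c_out, Ho, Wo, N);
  return List::create(_["out"] = out, _["patches"] = P);
}

// backward using a cached patch matrix (skips recomputing im2col)
// [[Rcpp::export]]
List cpp_conv2d_backward_patches(NumericMatrix patches, IntegerVector xdim,
                                 NumericVector w, int c_out, int k,
                                 NumericVector gout, int stride, int pad,
                                 bool want_dx) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat P(patches.begin(), patches.nrow(), patches.ncol(), false);
  arma::mat G(gout.begin(), c_out, (size_t)Ho * Wo * N, false);
  arma::mat Wm(w.begin(), c_out, C * k * k, false);
  arma::mat dW = G * P.t();
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(c_out, C, k, k);
  if (!want_dx) {
    return List::create(_["dx"] = R_NilValue, _["dw"] = dwv);
  }
  arma::mat Pg = Wm.t() * G;
  NumericVector dx((R_xlen_t)C * H * W * N);
  col2im(Pg, C, H, W, N, k, stride, pad, Ho, Wo, dx.begin());
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dx"] = dx, _["dw"] = dwv);
}

// Training-path kernels in single precision: the im2col patch matrix is
// kept on the C++ heap (external pointer) between the forward and backward
// passes of a batch, and the GEMMs run in float32.  Outputs are returned
// in double precision.

// [[Rcpp::export]]
List cpp_conv2d_forward_f(NumericVector x, IntegerVector xdim,
                          NumericVector w, int c_out, int k,
                          int stride, int pad) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::fmat* P = new arma::fmat(C * k * k, (size_t)Ho * Wo * N);
  im2col_t<arma::fmat, float>(x.begin(), C, H, W, N, k, stride, pad, Ho, Wo,
                              *P);
  arma::fmat Wf(c_out, C * k * k);
  std::copy(w.begin(), w.end(), Wf.begin());
  arma::fmat O = Wf * (*P);
  NumericVector out(O.size());
  std::copy(O.begin(), O.end(), out.begin());
  out.attr("dim") = IntegerVector::create(c_out, Ho, Wo, N);
  XPtr<arma::fmat> ptr(P, true);
  return List::create(_["out"] = out, _["patches"] = ptr);
}

// [[Rcpp::export]]
List cpp_conv2d_backward_f(SEXP pptr, IntegerVector xdim,
                           NumericVector w, int c_out, int k,
                           NumericVector gout, int stride, int pad,
                           bool want_dx) {
  XPtr<arma::fmat> P(pptr);
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::fmat G(c_out, (size_t)Ho * Wo * N);
  std::copy(gout.begin(), gout.end(), G.begin());
  arma::fmat dW = G * P->t();
  NumericVector dwv(dW.size());
  std::copy(dW.begin(), dW.end(), dwv.begin());
  dwv.attr("dim") = IntegerVector::create(c_out, C, k, k);
  if (!want_dx) {
    return List::create(_["dx"] = R_NilValue, _["dw"] = dwv);
  }
  arma::fmat Wf(c_out, C * k * k);
  std::copy(w.begin(), w.end(), Wf.begin());
  arma::fmat Pg = Wf.t() * G;
  NumericVector dx((R_xlen_t)C * H * W * N);
  // float col2im accumulated straight into the double gradient buffer
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = dxp + (size_t)n * C * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        size_t col = (size_t)oy + (size_t)Ho * ox + (size_t)Ho * Wo * n;
        const float* pc = Pg.colptr(col);
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= H) continue;
            const float* src = pc + (size_t)C * (ky + k * kx);
            double* dst = xn + (size_t)C * ((size_t)iy + (size_t)H * ix);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return List::create(_["dx"] = dx, _["dw"] = dwv);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim,
                         int k, int stride, int pad) {
  int C = xdim[0], H = xdim[1], W = xdim[2], N = xdim[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  R_xlen_t nout = (R_xlen_t)C * Ho * Wo * N;
  NumericVector out(nout);
  IntegerVector idx(nout);  // 0-based flat index into x of each max
  const double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)n * C * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kx = 0; kx < k; ++kx) {
            int ix = ox * stride + kx - pad;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              int iy = oy * stride + ky - pad;
              if (iy < 0 || iy >= H) continue;
              size_t ii = xoff + c + (size_t)C * ((size_t)iy + (size_t)H * ix);
              if (px[ii] > best) { best = px[ii]; besti = ii; }
            }
          }
          size_t oi = (size_t)c + (size_t)C * ((size_t)oy + (size_t)Ho * (ox + (size_t)Wo * n));
          out[oi] = best;
          idx[oi] = (int)besti;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  idx.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector idx, NumericVector gout,
                                   IntegerVector xdim) {
  R_xlen_t nin = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nin);
  for (R_xlen_t i = 0; i < gout.size(); ++i) dx[idx[i]] += gout[i];
  dx.attr("dim") = xdim;
  return dx;
}

// ---- batch-norm and ReLU helpers (training hot path) ----

// training-mode batch norm over a (C x M) matrix stored column-major with C
// rows; returns y, cached normalized values (float, external pointer), the
// inverse std, and the batch mean/variance
// [[Rcpp::export]]
List cpp_bn_train_forward(NumericVector z, int C,
                          NumericVector g, NumericVector beta, double eps) {
  size_t M = z.size() / C;
  std::vector<double> sum(C, 0.0), sq(C, 0.0);
  const double* zp = z.begin();
  for (size_t m = 0; m < M; ++m) {
    const double* col = zp + m * C;
    for (int c = 0; c < C; ++c) { sum[c] += col[c]; sq[c] += col[c] * col[c]; }
  }
  NumericVector mu(C), va(C), istd(C);
  for (int c = 0; c < C; ++c) {
    mu[c] = sum[c] / M;
    va[c] = sq[c] / M - mu[c] * mu[c];
    istd[c] = 1.0 / std::sqrt(va[c] + eps);
  }
  arma::fmat* X = new arma::fmat(C, M);
  NumericVector y(z.size());
  double* yp = y.begin();
  float* xp = X->memptr();
  for (size_t m = 0; m < M; ++m) {
    const double* col = zp + m * C;
    double* yc = yp + m * C;
    float* xc = xp + m * C;
    for (int c = 0; c < C; ++c) {
      double xh = (col[c] - mu[c]) * istd[c];
      xc[c] = (float)xh;
      yc[c] = g[c] * xh + beta[c];
    }
  }
  y.attr("dim") = z.attr("dim");
  XPtr<arma::fmat> ptr(X, true);
  return List::create(_["y"] = y, _["xhat"] = ptr, _["istd"] = istd,
                      _["mean"] = mu, _["var"] = va);
}

// backward through training-mode batch norm
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector dy, int C, NumericVector g,
                     SEXP xhat_ptr, NumericVector istd) {
  XPtr<arma::fmat> X(xhat_ptr);
  size_t M = dy.size() / C;
  const float* xp = X->memptr();
  const double* dp = dy.begin();
  std::vector<double> dbeta(C, 0.0), dg(C, 0.0);
  for (size_t m = 0; m < M; ++m) {
    const double* dc = dp + m * C;
    const float* xc = xp + m * C;
    for (int c = 0; c < C; ++c) { dbeta[c] += dc[c]; dg[c] += dc[c] * xc[c]; }
  }
  std::vector<double> m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = g[c] * dbeta[c] / M;        // mean of dxhat = g * mean(dy)
    m2[c] = g[c] * dg[c] / M;           // mean of dxhat * xhat
  }
  NumericVector dz(dy.size());
  double* dzp = dz.begin();
  for (size_t m = 0; m < M; ++m) {
    const double* dc = dp + m * C;
    const float* xc = xp + m * C;
    double* zc = dzp + m * C;
    for (int c = 0; c < C; ++c) {
      zc[c] = istd[c] * (g[c] * dc[c] - m1[c] - xc[c] * m2[c]);
    }
  }
  dz.attr("dim") = dy.attr("dim");
  return List::create(_["dz"] = dz,
                      _["dg"] = NumericVector(dg.begin(), dg.end()),
                      _["dbeta"] = NumericVector(dbeta.begin(), dbeta.end()));
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin(); double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector grad, NumericVector y) {
  NumericVector out(grad.size());
  const double* gp = grad.begin(); const double* yp = y.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < grad.size(); ++i) op[i] = yp[i] > 0 ? gp[i] : 0.0;
  out.attr("dim") = grad.attr("dim");
  return out;
}

// ---- instance norm: per-sample, per-channel standardization ----
// z has dim (C, HW, N) conceptually; stats are per (c, n) over HW.

// [[Rcpp::export]]
List cpp_in_train_forward(NumericVector z, int C, int HW, int N,
                          NumericVector g, NumericVector beta, double eps) {
  arma::fmat* X = new arma::fmat(C, (size_t)HW * N);
  NumericVector y(z.size());
  NumericMatrix istd(C, N);
  const double* zp = z.begin();
  double* yp = y.begin();
  float* xp = X->memptr();
  std::vector<double> sum(C), sq(C);
  for (int n = 0; n < N; ++n) {
    const double* zn = zp + (size_t)n * C * HW;
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(sq.begin(), sq.end(), 0.0);
    for (int m = 0; m < HW; ++m) {
      const double* col = zn + (size_t)m * C;
      for (int c = 0; c < C; ++c) { sum[c] += col[c]; sq[c] += col[c] * col[c]; }
    }
    std::vector<double> mu(C), is(C);
    for (int c = 0; c < C; ++c) {
      mu[c] = sum[c] / HW;
      double va = sq[c] / HW - mu[c] * mu[c];
      is[c] = 1.0 / std::sqrt(va + eps);
      istd(c, n) = is[c];
    }
    double* yn = yp + (size_t)n * C * HW;
    float* xn = xp + (size_t)n * C * HW;
    for (int m = 0; m < HW; ++m) {
      const double* col = zn + (size_t)m * C;
      double* yc = yn + (size_t)m * C;
      float* xc = xn + (size_t)m * C;
      for (int c = 0; c < C; ++c) {
        double xh = (col[c] - mu[c]) * is[c];
        xc[c] = (float)xh;
        yc[c] = g[c] * xh + beta[c];
      }
    }
  }
  y.attr("dim") = z.attr("dim");
  XPtr<arma::fmat> ptr(X, true);
  return List::create(_["y"] = y, _["xhat"] = ptr, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_in_backward(NumericVector dy, int C, int HW, int N,
                     NumericVector g, SEXP xhat_ptr, NumericMatrix istd) {
  XPtr<arma::fmat> X(xhat_ptr);
  const float* xp = X->memptr();
  const double* dp = dy.begin();
  NumericVector dz(dy.size());
  double* dzp = dz.begin();
  std::vector<double> dg(C, 0.0), dbeta(C, 0.0), s1(C), s2(C);
  for (int n = 0; n < N; ++n) {
    const double* dn = dp + (size_t)n * C * HW;
    const float* xn = xp + (size_t)n * C * HW;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int m = 0; m < HW; ++m) {
      const double* dc = dn + (size_t)m * C;
      const float* xc = xn + (size_t)m * C;
      for (int c = 0; c < C; ++c) { s1[c] += dc[c]; s2[c] += dc[c] * xc[c]; }
    }
    double* zn = dzp + (size_t)n * C * HW;
    for (int c = 0; c < C; ++c) { dbeta[c] += s1[c]; dg[c] += s2[c]; }
    for (int m = 0; m < HW; ++m) {
      const double* dc = dn + (size_t)m * C;
      const float* xc = xn + (size_t)m * C;
      double* zc = zn + (size_t)m * C;
      for (int c = 0; c < C; ++c) {
        zc[c] = istd(c, n) * g[c] * (dc[c] - s1[c] / HW - xc[c] * s2[c] / HW);
      }
    }
  }
  dz.attr("dim") = dy.attr("dim");
  return List::create(_["dz"] = dz,
                      _["dg"] = NumericVector(dg.begin(), dg.end()),
                      _["dbeta"] = NumericVector(dbeta.begin(), dbeta.end()));
}
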