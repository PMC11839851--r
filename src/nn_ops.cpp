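// Low-level tensor primitives for the compact ResNet engine.
//
// All image tensors are R arrays with dim (H, W, C, N), column-major.
// Convolution weights are (outC x inC*kh*kw) matrices whose column
// index unrolls as r = (c*kh + ki)*kw + kj, matching im2col() below.
// Arithmetic is single precision internally (BLAS sgemm); inputs and
// outputs cross the R boundary as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the transposed im2col matrix: L = outH*outW*N rows, K = C*kh*kw
// columns; row index l = oh + outH*(ow + outW*n), column index
// r = (c*kh + ki)*kw + kj.  The L x K layout makes the inner writes
// contiguous and feeds BLAS directly.
static void im2col(const double* x, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad,
                   arma::fmat& colT) {
  const int outH = conv_out(H, kh, stride, pad);
  const int outW = conv_out(W, kw, stride, pad);
  const size_t HW = (size_t)H * W;
  const size_t L = (size_t)outH * outW * N;
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int r = (c * kh + ki) * kw + kj;
        float* dst = colT.colptr(r);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + HW * (c + (size_t)C * n);
          for (int ow = 0; ow < outW; ++ow) {
            const int iw = ow * stride - pad + kj;
            float* d = dst + (size_t)outH * (ow + (size_t)outW * n);
            if (iw < 0 || iw >= W) {
              for (int oh = 0; oh < outH; ++oh) d[oh] = 0.0f;
              continue;
            }
            const double* xcol = xc + (size_t)iw * H;
            for (int oh = 0; oh < outH; ++oh) {
              const int ih = oh * stride - pad + ki;
              d[oh] = (ih < 0 || ih >= H) ? 0.0f : (float)xcol[ih];
            }
          }
        }
      }
    }
  }
  (void)L;
}

// Scatter-add an L x K column matrix back to image layout (gradient wrt x).
static void col2im(const arma::fmat& colT, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad,
                   std::vector<float>& dx) {
  const int outH = conv_out(H, kh, stride, pad);
  const int outW = conv_out(W, kw, stride, pad);
  const size_t HW = (size_t)H * W;
  std::fill(dx.begin(), dx.end(), 0.0f);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int r = (c * kh + ki) * kw + kj;
        const float* src = colT.colptr(r);
        for (int n = 0; n < N; ++n) {
          float* xc = dx.data() + HW * (c + (size_t)C * n);
          for (int ow = 0; ow < outW; ++ow) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            float* xcol = xc + (size_t)iw * H;
            const float* sp = src + (size_t)outH * (ow + (size_t)outW * n);
            for (int oh = 0; oh < outH; ++oh) {
              const int ih = oh * stride - pad + ki;
              if (ih >= 0 && ih < H) xcol[ih] += sp[oh];
            }
          }
        }
      }
    }
  }
}

static IntegerVector tensor_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix w,
                             int kh, int kw, int stride, int pad) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (w.ncol() != C * kh * kw)
    stop("weight has %d columns, expected inC*kh*kw = %d (input has %d channels)",
         w.ncol(), C * kh * kw, C);
  const int outC = w.nrow();
  const int outH = conv_out(H, kh, stride, pad);
  const int outW = conv_out(W, kw, stride, pad);
  const int K = C * kh * kw;
  const size_t L = (size_t)outH * outW * N;

  arma::fmat colT(L, K);
  im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, colT);
  arma::fmat wT(K, outC);
  for (int i = 0; i < outC; ++i)
    for (int j = 0; j < K; ++j) wT(j, i) = (float)w(i, j);
  arma::fmat yT = colT * wT;  // L x outC

  NumericVector out((size_t)outH * outW * outC * N);
  out.attr("dim") = IntegerVector::create(outH, outW, outC, N);
  double* o = out.begin();
  const size_t planeo = (size_t)outH * outW;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < outC; ++co) {
      double* op = o + planeo * (co + (size_t)outC * n);
      const float* yp = yT.colptr(co) + planeo * n;
      for (size_t p = 0; p < planeo; ++p) op[p] = yp[p];
    }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                    int kh, int kw, int stride, int pad, bool need_dx) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = tensor_dim(dy);
  const int outH = dd[0], outW = dd[1], outC = dd[2];
  const size_t L = (size_t)outH * outW * N;
  const int K = C * kh * kw;

  arma::fmat colT(L, K);
  im2col(x.begin(), H, W, C, N, kh, kw, stride, pad, colT);

  // dy as L x outC
  arma::fmat dyT(L, outC);
  const double* dyp = dy.begin();
  const size_t planeo = (size_t)outH * outW;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < outC; ++co) {
      const double* ip = dyp + planeo * (co + (size_t)outC * n);
      float* op = dyT.colptr(co) + planeo * n;
      for (size_t p = 0; p < planeo; ++p) op[p] = (float)ip[p];
    }

  arma::fmat dwf = dyT.t() * colT;  // outC x K
  NumericMatrix dw(outC, K);
  for (int i = 0; i < outC; ++i)
    for (int j = 0; j < K; ++j) dw(i, j) = dwf(i, j);

  NumericVector dx;
  if (need_dx) {
    arma::fmat wf(outC, K);
    for (int i = 0; i < outC; ++i)
      for (int j = 0; j < K; ++j) wf(i, j) = (float)w(i, j);
    arma::fmat dcolT = dyT * wf;  // L x K
    std::vector<float> acc((size_t)H * W * C * N);
    col2im(dcolT, H, W, C, N, kh, kw, stride, pad, acc);
    dx = NumericVector(acc.size());
    for (size_t i = 0; i < acc.size(); ++i) dx[i] = acc[i];
    dx.attr("dim") = d;
  }
  return List::create(_["dw"] = dw, _["dx"] = dx);
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar,
                double momentum, double eps, bool training) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector y(x.size());
  y.attr("dim") = d;
  NumericVector save_mean(C), save_invstd(C);
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);

  for (int c = 0; c < C; ++c) {
    double mean, varb;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + HW * (c + (size_t)C * n);
        for (size_t p = 0; p < HW; ++p) { s += xp[p]; s2 += xp[p] * xp[p]; }
      }
      mean = s / m;
      varb = s2 / m - mean * mean;
      if (varb < 0) varb = 0;
      new_rmean[c] = (1 - momentum) * rmean[c] + momentum * mean;
      const double varu = (m > 1) ? varb * m / (m - 1) : varb;
      new_rvar[c] = (1 - momentum) * rvar[c] + momentum * varu;
    } else {
      mean = rmean[c];
      varb = rvar[c];
    }
    const double invstd = 1.0 / std::sqrt(varb + eps);
    save_mean[c] = mean;
    save_invstd[c] = invstd;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      double* yp = y.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p)
        yp[p] = g * (xp[p] - mean) * invstd + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = save_mean,
                      _["invstd"] = save_invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector invstd) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);

  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;  // sum(dy), sum(dy * xhat)
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      const double* dp = dy.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) {
        const double xhat = (xp[p] - mean[c]) * invstd[c];
        s1 += dp[p];
        s2 += dp[p] * xhat;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double k = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      const double* dp = dy.begin() + HW * (c + (size_t)C * n);
      double* op = dx.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) {
        const double xhat = (xp[p] - mean[c]) * invstd[c];
        op[p] = k * (dp[p] - s1 / m - xhat * s2 / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 3x3 stride-2 pad-1 max pooling (the ResNet stem pool), with argmax
// bookkeeping for the backward pass.  Ties keep the first maximum.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int outH = conv_out(H, k, stride, pad);
  const int outW = conv_out(W, k, stride, pad);
  NumericVector y((size_t)outH * outW * C * N);
  y.attr("dim") = IntegerVector::create(outH, outW, C, N);
  IntegerVector idx(y.size());
  const size_t HW = (size_t)H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + (size_t)C * n);
      const size_t base = HW * (c + (size_t)C * n);
      for (int ow = 0; ow < outW; ++ow)
        for (int oh = 0; oh < outH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int ih = oh * stride - pad + ki;
              if (ih < 0 || ih >= H) continue;
              const double v = xp[(size_t)iw * H + ih];
              if (v > best) { best = v; bidx = base + (size_t)iw * H + ih; }
            }
          }
          // column-major output offset: oh + outH*(ow + outW*(c + C*n))
          const size_t oo =
            (size_t)oh + (size_t)outH * (ow + (size_t)outW * (c + (size_t)C * n));
          y[oo] = best;
          idx[oo] = (int)bidx;
          ++o;
        }
    }
  (void)o;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Elementwise ReLU and fused residual-add + ReLU (single pass, keeps dim).
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_add_relu(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("size mismatch in residual add");
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const double* ap = a.begin();
  const double* bp = b.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const double s = ap[i] + bp[i];
    yp[i] = s > 0 ? s : 0.0;
  }
  return y;
}

// dy masked by (mask > 0), single pass.
// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector mask) {
  NumericVector y(dy.size());
  y.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* mp = mask.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) yp[i] = mp[i] > 0 ? dp[i] : 0.0;
  return y;
}

// One fused Adam step for a single parameter tensor (bias-corrected).
// Returns updated (p, m, v) computed in a single pass.
// [[Rcpp::export]]
List cpp_adam(NumericVector p, NumericVector g, NumericVector m,
              NumericVector v, double lr, double b1, double b2,
              double eps, double c1, double c2) {
  R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  p2.attr("dim") = p.attr("dim");
  const double *pp = p.begin(), *gp = g.begin(), *mp = m.begin(),
               *vp = v.begin();
  double *po = p2.begin(), *mo = m2.begin(), *vo = v2.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = b1 * mp[i] + (1 - b1) * gp[i];
    const double vi = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    mo[i] = mi;
    vo[i] = vi;
    po[i] = pp[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
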