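// Numerical kernels for the encoder-decoder segmentation network.
//
// Layout conventions (match R's column-major arrays):
//   activations  x[H, W, C, N]
//   conv weights w[k, k, Cin, Cout]
//   transpose-conv weights w[k, k, Cout, Cin] (input channels last so that the
//     column-major flattening gives the (k*k*Cout) x Cin matrix used below)
//
// "Same" convolutions (zero padding (k-1)/2, stride 1) use a shift-gemm
// scheme: the input is copied once into a zero-padded buffer with the same
// column stride as the padded output, after which every kernel offset is one
// BLAS dgemm on shifted views of those buffers. This avoids materializing
// im2col matrices (k^2 larger than the activations) in both passes.
// The stride-2 3x3 transpose convolution is small and keeps a classic
// gather/scatter (im2col/col2im) formulation.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#ifndef FCLEN
#define FCLEN
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// The stride-1 convolutions accumulate in single precision: activations are
// converted at the padded-buffer copy, the per-offset products run through
// BLAS sgemm, and results convert back to double at the boundary. Halving
// the streamed bytes nearly halves the conv cost at these channel widths,
// and the ~1e-6 relative rounding is far below any gradient noise that
// matters at the training scale used here.
extern "C" void F77_NAME(sgemm)(const char* transa, const char* transb,
                                const int* m, const int* n, const int* k,
                                const float* alpha, const float* a, const int* lda,
                                const float* b, const int* ldb, const float* beta,
                                float* c, const int* ldc FCLEN FCLEN);

// Copy an [H, W, C] slab into a zero-padded [Hp, Wp, C] float buffer.
static void pad_slab(const double* x, int H, int W, int C, int p,
                     std::vector<float>& xp) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t P = static_cast<size_t>(Hp) * Wp;
  std::fill(xp.begin(), xp.end(), 0.0f);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w) {
      const double* src = x + (static_cast<size_t>(c) * W + w) * H;
      float* dst = xp.data() + c * P + static_cast<size_t>(w + p) * Hp + p;
      for (int i = 0; i < H; ++i) dst[i] = static_cast<float>(src[i]);
    }
}

// Extract the interior [H, W, C] slab of a padded float buffer.
static void unpad_slab(const std::vector<float>& xp, int H, int W, int C, int p,
                       double* x) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t P = static_cast<size_t>(Hp) * Wp;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w) {
      const float* src = xp.data() + c * P + static_cast<size_t>(w + p) * Hp + p;
      double* dst = x + (static_cast<size_t>(c) * W + w) * H;
      for (int i = 0; i < H; ++i) dst[i] = static_cast<double>(src[i]);
    }
}

// The (Cin x Cout) weight slice for one kernel offset (ki, kj).
static void weight_slice(const double* w, int k, int Cin, int Cout,
                         int ki, int kj, std::vector<float>& wt) {
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      wt[static_cast<size_t>(co) * Cin + ci] = static_cast<float>(
        w[ki + static_cast<size_t>(k) * kj + static_cast<size_t>(k) * k * ci +
          static_cast<size_t>(k) * k * Cin * co]);
}

static void sgemm_(char ta, char tb, int m, int n, int kk, float alpha,
                   const float* A, int lda, const float* B, int ldb,
                   float beta, float* C, int ldc) {
  F77_CALL(sgemm)(&ta, &tb, &m, &n, &kk, &alpha, A, &lda,
                  B, &ldb, &beta, C, &ldc FCONE FCONE);
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const int p = (k - 1) / 2;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t P = static_cast<size_t>(Hp) * Wp;

  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  std::vector<float> xp(P * C), yp(P * Cout), wt(static_cast<size_t>(C) * Cout);
  for (int n = 0; n < N; ++n) {
    pad_slab(x.begin() + static_cast<size_t>(n) * H * W * C, H, W, C, p, xp);
    std::fill(yp.begin(), yp.end(), 0.0f);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const long d = static_cast<long>(kj - p) * Hp + (ki - p);
        const int m = static_cast<int>(P) - static_cast<int>(std::labs(d));
        weight_slice(w.begin(), k, Cin, Cout, ki, kj, wt);
        sgemm_('N', 'N', m, Cout, C, 1.0f,
               xp.data() + std::max(d, 0L), static_cast<int>(P),
               wt.data(), C, 1.0f,
               yp.data() + std::max(-d, 0L), static_cast<int>(P));
      }
    }
    double* yn = y.begin() + static_cast<size_t>(n) * H * W * Cout;
    unpad_slab(yp, H, W, Cout, p, yn);
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      double* yc = yn + static_cast<size_t>(co) * H * W;
      for (size_t i = 0; i < static_cast<size_t>(H) * W; ++i) yc[i] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 bool need_dx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int p = (k - 1) / 2;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t P = static_cast<size_t>(Hp) * Wp;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  std::vector<float> xp(P * C), dyp(P * Cout), dxp(P * C),
      wt(static_cast<size_t>(C) * Cout), dwt(static_cast<size_t>(C) * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + static_cast<size_t>(n) * H * W * Cout;
    pad_slab(x.begin() + static_cast<size_t>(n) * H * W * C, H, W, C, p, xp);
    pad_slab(dyn, H, W, Cout, p, dyp);
    std::fill(dxp.begin(), dxp.end(), 0.0f);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const long d = static_cast<long>(kj - p) * Hp + (ki - p);
        const int m = static_cast<int>(P) - static_cast<int>(std::labs(d));
        weight_slice(w.begin(), k, C, Cout, ki, kj, wt);
        // input gradient: dxp[q + d] += dyp[q] * W_off^T
        if (need_dx)
          sgemm_('N', 'T', m, C, Cout, 1.0f,
                 dyp.data() + std::max(-d, 0L), static_cast<int>(P),
                 wt.data(), C, 1.0f,
                 dxp.data() + std::max(d, 0L), static_cast<int>(P));
        // weight gradient: dW_off += Xs^T * dy (padded dy is zero off-interior)
        sgemm_('T', 'N', C, Cout, m, 1.0f,
               xp.data() + std::max(d, 0L), static_cast<int>(P),
               dyp.data() + std::max(-d, 0L), static_cast<int>(P),
               0.0f, dwt.data(), C);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            dw[ki + static_cast<size_t>(k) * kj + static_cast<size_t>(k) * k * ci +
               static_cast<size_t>(k) * k * C * co] += dwt[static_cast<size_t>(co) * C + ci];
      }
    }
    if (need_dx)
      unpad_slab(dxp, H, W, C, p, dx.begin() + static_cast<size_t>(n) * H * W * C);
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + static_cast<size_t>(co) * H * W;
      double s = 0.0;
      for (size_t i = 0; i < static_cast<size_t>(H) * W; ++i) s += dyc[i];
      db[co] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- stride-2 transpose convolution (kernel 3, pad 1, output 2x input) ----

// Gather output columns into M ((Hout*Wout) x k*k*C) for stride-2 access.
static void im2col_s2(const double* x, int H, int W, int C,
                      int k, int pad, int Hout, int Wout, arma::mat& M) {
  M.set_size(static_cast<arma::uword>(Hout) * Wout, static_cast<arma::uword>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + static_cast<size_t>(c) * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword colidx = (static_cast<arma::uword>(c) * k + kj) * k + ki;
        double* mcol = M.colptr(colidx);
        for (int wo = 0; wo < Wout; ++wo) {
          const int in_col = wo * 2 - pad + kj;
          double* mdst = mcol + static_cast<size_t>(wo) * Hout;
          if (in_col < 0 || in_col >= W) {
            std::fill(mdst, mdst + Hout, 0.0);
            continue;
          }
          const double* xcol = xc + static_cast<size_t>(in_col) * H;
          for (int ho = 0; ho < Hout; ++ho) {
            const int in_row = ho * 2 - pad + ki;
            mdst[ho] = (in_row >= 0 && in_row < H) ? xcol[in_row] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_s2(const arma::mat& M, double* x, int H, int W, int C,
                      int k, int pad, int Hout, int Wout) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + static_cast<size_t>(c) * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const arma::uword colidx = (static_cast<arma::uword>(c) * k + kj) * k + ki;
        const double* mcol = M.colptr(colidx);
        for (int wo = 0; wo < Wout; ++wo) {
          const int in_col = wo * 2 - pad + kj;
          if (in_col < 0 || in_col >= W) continue;
          double* xcol = xc + static_cast<size_t>(in_col) * H;
          const double* msrc = mcol + static_cast<size_t>(wo) * Hout;
          for (int ho = 0; ho < Hout; ++ho) {
            const int in_row = ho * 2 - pad + ki;
            if (in_row >= 0 && in_row < H) xcol[in_row] += msrc[ho];
          }
        }
      }
    }
  }
}

// Transpose convolution, kernel 3, stride 2, pad 1, output_padding 1:
// maps [H, W, Cin] -> [2H, 2W, Cout]. Weights w[3, 3, Cout, Cin].
// [[Rcpp::export]]
NumericVector nn_tconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  if (wd[3] != Cin) stop("channel mismatch between input and transpose-conv weights");
  const int Hb = 2 * H, Wb = 2 * W;
  arma::mat Wm(const_cast<double*>(w.begin()), static_cast<arma::uword>(k) * k * Cout, Cin, false, true);

  NumericVector y(static_cast<R_xlen_t>(Hb) * Wb * Cout * N);
  y.attr("dim") = IntegerVector::create(Hb, Wb, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + static_cast<size_t>(n) * H * W * Cin,
                 static_cast<arma::uword>(H) * W, Cin, false, true);
    arma::mat M = Xm * Wm.t();  // (H*W) x (k*k*Cout)
    double* yn = y.begin() + static_cast<size_t>(n) * Hb * Wb * Cout;
    col2im_s2(M, yn, Hb, Wb, Cout, k, 1, H, W);
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + static_cast<size_t>(co) * Hb * Wb;
      const double bc = b[co];
      for (size_t i = 0; i < static_cast<size_t>(Hb) * Wb; ++i) yc[i] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_tconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[2];
  const int Hb = 2 * H, Wb = 2 * W;
  arma::mat Wm(const_cast<double*>(w.begin()), static_cast<arma::uword>(k) * k * Cout, Cin, false, true);

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dWm(static_cast<arma::uword>(k) * k * Cout, Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + static_cast<size_t>(n) * Hb * Wb * Cout;
    im2col_s2(dyn, Hb, Wb, Cout, k, 1, H, W, M);  // (H*W) x (k*k*Cout)
    arma::mat Xm(const_cast<double*>(x.begin()) + static_cast<size_t>(n) * H * W * Cin,
                 static_cast<arma::uword>(H) * W, Cin, false, true);
    arma::mat dXm(dx.begin() + static_cast<size_t>(n) * H * W * Cin,
                  static_cast<arma::uword>(H) * W, Cin, false, true);
    dXm += M * Wm;
    dWm += M.t() * Xm;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + static_cast<size_t>(co) * Hb * Wb;
      double s = 0.0;
      for (size_t i = 0; i < static_cast<size_t>(Hb) * Wb; ++i) s += dyc[i];
      db[co] += s;
    }
  }
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax indices
// into the input sample-slab so the backward pass is an exact scatter.
// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  const size_t slab = static_cast<size_t>(H) * W * C;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + n * slab;
    double* yn = y.begin() + static_cast<size_t>(n) * Ho * Wo * C;
    int* in = idx.begin() + static_cast<size_t>(n) * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t base = static_cast<size_t>(c) * H * W;
          size_t best = base + static_cast<size_t>(2 * wo) * H + 2 * ho;
          double bv = xn[best];
          const int dr[3] = {1, 0, 1};
          const int dc[3] = {0, 1, 1};
          for (int t = 0; t < 3; ++t) {
            size_t cand = base + static_cast<size_t>(2 * wo + dc[t]) * H + 2 * ho + dr[t];
            if (xn[cand] > bv) { bv = xn[cand]; best = cand; }
          }
          const size_t o = static_cast<size_t>(c) * Ho * Wo + static_cast<size_t>(wo) * Ho + ho;
          yn[o] = bv;
          in[o] = static_cast<int>(best) + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t slab = static_cast<size_t>(H) * W * C;
  const size_t oslab = static_cast<size_t>(Ho) * Wo * C;
  for (int n = 0; n < N; ++n) {
    double* dxn = dx.begin() + n * slab;
    const double* dyn = dy.begin() + n * oslab;
    const int* in = idx.begin() + n * oslab;
    for (size_t o = 0; o < oslab; ++o) dxn[in[o] - 1] += dyn[o];
  }
  return dx;
}

// ---- batch normalization (per-channel over H, W, N) ----

// Forward: y = (x - mean) * invstd * gamma + beta, one pass, returning the
// normalized activations xhat alongside (needed by the backward pass).
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector mean, NumericVector var, double eps,
               bool want_xhat = true) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector xhat;
  if (want_xhat) { xhat = NumericVector(x.size()); xhat.attr("dim") = xd; }
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double mu = mean[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* yc = y.begin() + (static_cast<size_t>(n) * C + c) * HW;
      if (want_xhat) {
        double* hc = xhat.begin() + (static_cast<size_t>(n) * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) {
          const double h = (xc[i] - mu) * inv;
          hc[i] = h;
          yc[i] = h * g + b;
        }
      } else {
        const double a = g * inv, bb = b - mu * inv * g;
        for (size_t i = 0; i < HW; ++i) yc[i] = xc[i] * a + bb;
      }
    }
  }
  if (want_xhat) return List::create(_["y"] = y, _["xhat"] = xhat);
  return List::create(_["y"] = y, _["xhat"] = R_NilValue);
}

// Per-channel batch mean and (biased) variance in one pass.
// [[Rcpp::export]]
List nn_bn_moments(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    const double m = s / (HW * N);
    mean[c] = m;
    var[c] = std::max(s2 / (HW * N) - m * m, 0.0);
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// Backward through batch statistics:
// dx = gamma * invstd / m * (m * dy - sum(dy) - xhat * sum(dy * xhat))
// [[Rcpp::export]]
List nn_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
               NumericVector gamma) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = static_cast<size_t>(H) * W;
  const double m = static_cast<double>(HW) * N;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* dc = dy.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double* hc = xhat.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double a = gamma[c] * invstd[c] / m;
    for (int n = 0; n < N; ++n) {
      const double* dc = dy.begin() + (static_cast<size_t>(n) * C + c) * HW;
      const double* hc = xhat.begin() + (static_cast<size_t>(n) * C + c) * HW;
      double* xc = dx.begin() + (static_cast<size_t>(n) * C + c) * HW;
      for (size_t i = 0; i < HW; ++i)
        xc[i] = a * (m * dc[i] - sb - hc[i] * sg);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- cheap elementwise/layout helpers (hot in the training loop) ----

// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xi = x.begin();
  double* yi = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yi[i] = xi[i] > 0 ? xi[i] : 0.0;
  return y;
}

// Gradient through ReLU given its output: dy where y > 0, else 0.
// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* d = dy.begin();
  const double* yy = y.begin();
  double* o = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) o[i] = yy[i] > 0 ? d[i] : 0.0;
  return dx;
}

// Concatenate two [H, W, C, N] stacks along the channel axis.
// [[Rcpp::export]]
NumericVector nn_concat(NumericVector a, NumericVector b) {
  IntegerVector ad = a.attr("dim"), bd = b.attr("dim");
  const int H = ad[0], W = ad[1], Ca = ad[2], Cb = bd[2], N = ad[3];
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector z(static_cast<R_xlen_t>(HW) * (Ca + Cb) * N);
  z.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + n * HW * Ca, a.begin() + (n + 1) * HW * Ca,
              z.begin() + static_cast<size_t>(n) * HW * (Ca + Cb));
    std::copy(b.begin() + n * HW * Cb, b.begin() + (n + 1) * HW * Cb,
              z.begin() + static_cast<size_t>(n) * HW * (Ca + Cb) + HW * Ca);
  }
  return z;
}

// Split a channel-concatenated stack back into its two parts.
// [[Rcpp::export]]
List nn_split(NumericVector z, int Ca) {
  IntegerVector zd = z.attr("dim");
  const int H = zd[0], W = zd[1], C = zd[2], N = zd[3];
  const int Cb = C - Ca;
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector a(static_cast<R_xlen_t>(HW) * Ca * N), b(static_cast<R_xlen_t>(HW) * Cb * N);
  a.attr("dim") = IntegerVector::create(H, W, Ca, N);
  b.attr("dim") = IntegerVector::create(H, W, Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(z.begin() + static_cast<size_t>(n) * HW * C,
              z.begin() + static_cast<size_t>(n) * HW * C + HW * Ca,
              a.begin() + static_cast<size_t>(n) * HW * Ca);
    std::copy(z.begin() + static_cast<size_t>(n) * HW * C + HW * Ca,
              z.begin() + static_cast<size_t>(n + 1) * HW * C,
              b.begin() + static_cast<size_t>(n) * HW * Cb);
  }
  return List::create(_["a"] = a, _["b"] = b);
}
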