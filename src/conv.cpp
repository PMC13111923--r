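// Convolution and batch-norm kernels for the EEGNet-style network.
//
// Layout conventions (column-major, time fastest):
//   column tensors : x [T, M]            one time series per column
//   bank output    : y [T, M, F]         F filters applied to every column
//   4-D activation : A [T, C, N, F1]     temporal-conv output
//   spatial output : Z [T, D*F1, N]      depthwise spatial contraction
//
// Tensors cross the boundary as flat numeric vectors plus explicit
// geometry, so no copies or reshapes are needed on either side.
// "Same" padding: y[t] = sum_k x[t + k - padL] * w[k], zero-padded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_block(const double* X, const int T, const int m0,
                                const int nb, const int K, const int padL,
                                arma::mat& col) {
  for (int k = 0; k < K; ++k) {
    const int off = k - padL;
    const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
    for (int b = 0; b < nb; ++b) {
      const double* xc = X + (size_t)(m0 + b) * T;
      double* cc = col.colptr(k) + (size_t)b * T;
      if (t0 > 0) std::fill(cc, cc + t0, 0.0);
      std::copy(xc + t0 + off, xc + t1 + off, cc + t0);
      if (t1 < T) std::fill(cc + t1, cc + T, 0.0);
    }
  }
}

// y[t, m, f] = sum_k x[t + k - padL, m] * W[k, f]
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(const NumericVector& x, const int T, const int M,
                           const NumericMatrix& W, const int padL) {
  const int K = W.nrow(), F = W.ncol();
  NumericVector y(no_init((R_xlen_t)T * M * F));
  const arma::mat Wa(const_cast<double*>(W.begin()), K, F, false, true);
  const int block = std::max(1, (int)(4e6 / (double)(T * K)));
  arma::mat col;
  for (int m0 = 0; m0 < M; m0 += block) {
    const int nb = std::min(block, M - m0);
    col.set_size(T * nb, K);
    im2col_block(x.begin(), T, m0, nb, K, padL, col);
    arma::mat out = col * Wa;  // [T*nb, F]
    for (int f = 0; f < F; ++f)
      std::copy(out.colptr(f), out.colptr(f) + (size_t)T * nb,
                y.begin() + (size_t)f * T * M + (size_t)m0 * T);
  }
  return y;
}

// dx[s, m] = sum_{t,f,k: t+k-padL=s} dy[t, m, f] * W[k, f]
// (loops ordered so the dx column stays cache-resident)
// [[Rcpp::export]]
NumericVector cpp_conv_gradin(const NumericVector& dy, const int T,
                              const int M, const NumericMatrix& W,
                              const int padL) {
  const int K = W.nrow(), F = W.ncol();
  NumericVector dx((R_xlen_t)T * M);  // zero-initialized
  for (int m = 0; m < M; ++m) {
    double* dp = dx.begin() + (size_t)m * T;
    for (int f = 0; f < F; ++f) {
      const double* sp = dy.begin() + (size_t)f * T * M + (size_t)m * T;
      for (int k = 0; k < K; ++k) {
        const double w = W(k, f);
        if (w == 0.0) continue;
        const int off = k - padL;
        const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
        double* dpo = dp + off;
        for (int t = t0; t < t1; ++t) dpo[t] += sp[t] * w;
      }
    }
  }
  return dx;
}

// dW[k, f] = sum_{t,m} x[t + k - padL, m] * dy[t, m, f]
// [[Rcpp::export]]
NumericMatrix cpp_conv_gradw(const NumericVector& x, const NumericVector& dy,
                             const int T, const int M, const int K,
                             const int F, const int padL) {
  arma::mat dW(K, F, arma::fill::zeros);
  const int block = std::max(1, (int)(4e6 / (double)(T * K)));
  arma::mat col, dYm;
  for (int m0 = 0; m0 < M; m0 += block) {
    const int nb = std::min(block, M - m0);
    col.set_size(T * nb, K);
    dYm.set_size(T * nb, F);
    im2col_block(x.begin(), T, m0, nb, K, padL, col);
    for (int f = 0; f < F; ++f)
      std::copy(dy.begin() + (size_t)f * T * M + (size_t)m0 * T,
                dy.begin() + (size_t)f * T * M + (size_t)(m0 + nb) * T,
                dYm.colptr(f));
    dW += col.t() * dYm;
  }
  return wrap(dW);
}

// Z[t, (f1-1)*D + d, n] = sum_c A[t, c, n, f1] * Ws[c, d, f1]
// [[Rcpp::export]]
NumericVector cpp_spatial_fwd(const NumericVector& A, const arma::cube& Ws,
                              const IntegerVector& dims) {
  const int T = dims[0], C = dims[1], N = dims[2], F1 = dims[3];
  const int D = Ws.n_cols;
  NumericVector Zv(no_init((R_xlen_t)T * D * F1 * N));
  const double* ap = A.begin();
  double* zp = Zv.begin();
  const arma::uword strN = (arma::uword)T * C, strF = strN * N;
  for (int f1 = 0; f1 < F1; ++f1) {
    const arma::mat Wf = Ws.slice(f1);  // [C, D]
    for (int n = 0; n < N; ++n) {
      const arma::mat Ablk(const_cast<double*>(ap) + (arma::uword)n * strN +
                               (arma::uword)f1 * strF,
                           T, C, false, true);
      arma::mat Zblk(zp + (arma::uword)n * T * D * F1 +
                         (arma::uword)f1 * D * T,
                     T, D, false, true);
      Zblk = Ablk * Wf;
    }
  }
  return Zv;
}

// dA[t, c, n, f1] = sum_d dZ[t, (f1-1)*D + d, n] * Ws[c, d, f1]
// [[Rcpp::export]]
NumericVector cpp_spatial_gradin(const NumericVector& dZ, const arma::cube& Ws,
                                 const IntegerVector& dims) {
  const int T = dims[0], C = dims[1], N = dims[2], F1 = dims[3];
  const int D = Ws.n_cols;
  NumericVector dAv(no_init((R_xlen_t)T * C * N * F1));
  const double* zp = dZ.begin();
  double* ap = dAv.begin();
  const arma::uword strN = (arma::uword)T * C, strF = strN * N;
  for (int f1 = 0; f1 < F1; ++f1) {
    const arma::mat Wf = Ws.slice(f1);
    for (int n = 0; n < N; ++n) {
      const arma::mat Zblk(const_cast<double*>(zp) +
                               (arma::uword)n * T * D * F1 +
                               (arma::uword)f1 * D * T,
                           T, D, false, true);
      arma::mat Ablk(ap + (arma::uword)n * strN + (arma::uword)f1 * strF,
                     T, C, false, true);
      Ablk = Zblk * Wf.t();
    }
  }
  return dAv;
}

// dWs[c, d, f1] = sum_{t,n} A[t, c, n, f1] * dZ[t, (f1-1)*D + d, n]
// [[Rcpp::export]]
arma::cube cpp_spatial_gradw(const NumericVector& A, const NumericVector& dZ,
                             const IntegerVector& dims, const int D) {
  const int T = dims[0], C = dims[1], N = dims[2], F1 = dims[3];
  arma::cube dWs(C, D, F1, arma::fill::zeros);
  const double* ap = A.begin();
  const double* zp = dZ.begin();
  const arma::uword strN = (arma::uword)T * C, strF = strN * N;
  for (int f1 = 0; f1 < F1; ++f1) {
    arma::mat acc(C, D, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const arma::mat Ablk(const_cast<double*>(ap) + (arma::uword)n * strN +
                               (arma::uword)f1 * strF,
                           T, C, false, true);
      const arma::mat Zblk(const_cast<double*>(zp) +
                               (arma::uword)n * T * D * F1 +
                               (arma::uword)f1 * D * T,
                           T, D, false, true);
      acc += Ablk.t() * Zblk;
    }
    dWs.slice(f1) = acc;
  }
  return dWs;
}

// fused batch-norm forward over a column-per-feature flat tensor
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericVector& x, const NumericVector& gamma,
                const NumericVector& beta, const NumericVector& rmean,
                const NumericVector& rvar, const double eps,
                const bool training) {
  const int F = gamma.size();
  const size_t R = x.size() / F;
  NumericVector y(no_init(x.size()));
  NumericVector mu(F), va(F);
  for (int f = 0; f < F; ++f) {
    const double* xp = x.begin() + R * f;
    double m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < R; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      m = s / R;
      v = s2 / R - m * m;
    } else {
      m = rmean[f]; v = rvar[f];
    }
    mu[f] = m; va[f] = v;
    const double sc = gamma[f] / std::sqrt(v + eps);
    const double sh = beta[f] - m * sc;
    double* yp = y.begin() + R * f;
    for (size_t i = 0; i < R; ++i) yp[i] = xp[i] * sc + sh;
  }
  return List::create(Named("y") = y, Named("mu") = mu,
                      Named("var") = va);
}

// fused batch-norm backward; xhat recovered from the stored output
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericVector& dy, const NumericVector& y,
                const NumericVector& mu, const NumericVector& va,
                const NumericVector& gamma, const NumericVector& beta,
                const double eps) {
  const int F = gamma.size();
  const size_t R = dy.size() / F;
  NumericVector dx(no_init(dy.size()));
  NumericVector dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    const double* dp = dy.begin() + R * f;
    const double* yp = y.begin() + R * f;
    const double g = gamma[f], b = beta[f];
    const double gi = 1.0 / g;
    double sdy = 0.0, sdyx = 0.0;
    for (size_t i = 0; i < R; ++i) {
      const double xh = (yp[i] - b) * gi;
      sdy += dp[i];
      sdyx += dp[i] * xh;
    }
    dgamma[f] = sdyx;
    dbeta[f] = sdy;
    const double isd = 1.0 / std::sqrt(va[f] + eps);
    const double m1 = g * sdy / R, m2 = sdyx / R;
    double* op = dx.begin() + R * f;
    const double gm2 = g * m2 * gi;
    for (size_t i = 0; i < R; ++i) {
      op[i] = (dp[i] * g - m1 - (yp[i] - b) * gm2) * isd;
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
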