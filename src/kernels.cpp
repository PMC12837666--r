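// Compute kernels for the sequence models and convolution blocks.
//
// Layout conventions (all column-major, matching R arrays):
//   signal tensors   [F, C, T, B]  (feature fastest, then electrode, time, window)
//   sequence tensors [E, T, B]     (inner channel fastest)
// The SSM scan and the WKV recurrence are inherently sequential in t; they are
// written as straight loops here and verified against naive R oracles in the
// test suite. Convolutions are lowered to im2col + BLAS dgemm.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

static void dgemm_nn(int m, int n, int k, double alpha, const double* A, int lda,
                     const double* B, int ldb, double beta, double* C, int ldc) {
  const char* tn = "N";
  F77_CALL(dgemm)(tn, tn, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc FCONE FCONE);
}

static void dgemm_tn(int m, int n, int k, double alpha, const double* A, int lda,
                     const double* B, int ldb, double beta, double* C, int ldc) {
  const char* tt = "T";
  const char* tn = "N";
  F77_CALL(dgemm)(tt, tn, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc FCONE FCONE);
}

static void dgemm_nt(int m, int n, int k, double alpha, const double* A, int lda,
                     const double* B, int ldb, double beta, double* C, int ldc) {
  const char* tn = "N";
  const char* tt = "T";
  F77_CALL(dgemm)(tn, tt, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc FCONE FCONE);
}

// ---------------------------------------------------------------------------
// im2col builders. Tile has rows (f, k) and columns (c, t); the "time" variant
// shifts along t, the "space" variant along c. Out-of-range taps are zero
// (same padding with offset (K-1)/2).

static void im2col_time(const double* x, int F, int C, int T, int K, int off,
                        double* tile) {
  // tile[(f + F*k), (c + C*t)] = x[f, c, t + k - off]
  const int FK = F * K;
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      double* col = tile + (std::size_t)FK * (c + (std::size_t)C * t);
      for (int k = 0; k < K; ++k) {
        int tt = t + k - off;
        if (tt < 0 || tt >= T) {
          std::memset(col + F * k, 0, sizeof(double) * F);
        } else {
          std::memcpy(col + F * k, x + (std::size_t)F * (c + (std::size_t)C * tt),
                      sizeof(double) * F);
        }
      }
    }
  }
}

static void im2col_space(const double* x, int F, int C, int T, int K, int off,
                         double* tile) {
  // tile[(f + F*k), (c + C*t)] = x[f, c + k - off, t]
  const int FK = F * K;
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      double* col = tile + (std::size_t)FK * (c + (std::size_t)C * t);
      for (int k = 0; k < K; ++k) {
        int cc = c + k - off;
        if (cc < 0 || cc >= C) {
          std::memset(col + F * k, 0, sizeof(double) * F);
        } else {
          std::memcpy(col + F * k, x + (std::size_t)F * (cc + (std::size_t)C * t),
                      sizeof(double) * F);
        }
      }
    }
  }
}

static void col2im_time(const double* tile, int F, int C, int T, int K, int off,
                        double* dx) {
  const int FK = F * K;
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* col = tile + (std::size_t)FK * (c + (std::size_t)C * t);
      for (int k = 0; k < K; ++k) {
        int tt = t + k - off;
        if (tt < 0 || tt >= T) continue;
        double* dst = dx + (std::size_t)F * (c + (std::size_t)C * tt);
        const double* src = col + F * k;
        for (int f = 0; f < F; ++f) dst[f] += src[f];
      }
    }
  }
}

static void col2im_space(const double* tile, int F, int C, int T, int K, int off,
                         double* dx) {
  const int FK = F * K;
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* col = tile + (std::size_t)FK * (c + (std::size_t)C * t);
      for (int k = 0; k < K; ++k) {
        int cc = c + k - off;
        if (cc < 0 || cc >= C) continue;
        double* dst = dx + (std::size_t)F * (cc + (std::size_t)C * t);
        const double* src = col + F * k;
        for (int f = 0; f < F; ++f) dst[f] += src[f];
      }
    }
  }
}

// Shared conv driver: axis = 0 -> shift along time, axis = 1 -> shift along C.
static NumericVector conv_fwd_impl(const NumericVector& x, int Fi, int C, int T,
                                   int B, const NumericVector& W, int Fo, int K,
                                   const NumericVector& bias, int axis) {
  const int off = (K - 1) / 2;
  const int FK = Fi * K;
  const std::size_t block = (std::size_t)C * T;
  NumericVector y((std::size_t)Fo * C * T * B);
  std::vector<double> tile((std::size_t)FK * block);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (std::size_t)Fi * block * b;
    double* yb = yp + (std::size_t)Fo * block * b;
    if (axis == 0) im2col_time(xb, Fi, C, T, K, off, tile.data());
    else im2col_space(xb, Fi, C, T, K, off, tile.data());
    dgemm_nn(Fo, (int)block, FK, 1.0, W.begin(), Fo, tile.data(), FK, 0.0, yb, Fo);
    for (std::size_t j = 0; j < block; ++j)
      for (int f = 0; f < Fo; ++f) yb[f + (std::size_t)Fo * j] += bias[f];
  }
  return y;
}

static List conv_bwd_impl(const NumericVector& x, int Fi, int C, int T, int B,
                          const NumericVector& W, int Fo, int K,
                          const NumericVector& dy, int axis) {
  const int off = (K - 1) / 2;
  const int FK = Fi * K;
  const std::size_t block = (std::size_t)C * T;
  NumericVector dx((std::size_t)Fi * block * B);
  NumericVector dW((std::size_t)Fo * FK);
  NumericVector db(Fo);
  std::vector<double> tile((std::size_t)FK * block);
  std::vector<double> dtile((std::size_t)FK * block);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + (std::size_t)Fi * block * b;
    const double* dyb = dyp + (std::size_t)Fo * block * b;
    if (axis == 0) im2col_time(xb, Fi, C, T, K, off, tile.data());
    else im2col_space(xb, Fi, C, T, K, off, tile.data());
    // dW += dyb [Fo x block] * tile^T [block x FK]
    dgemm_nt(Fo, FK, (int)block, 1.0, dyb, Fo, tile.data(), FK, 1.0, dW.begin(), Fo);
    // dtile = W^T [FK x Fo] * dyb [Fo x block]
    dgemm_tn(FK, (int)block, Fo, 1.0, W.begin(), Fo, dyb, Fo, 0.0, dtile.data(), FK);
    double* dxb = dx.begin() + (std::size_t)Fi * block * b;
    if (axis == 0) col2im_time(dtile.data(), Fi, C, T, K, off, dxb);
    else col2im_space(dtile.data(), Fi, C, T, K, off, dxb);
    for (std::size_t j = 0; j < block; ++j)
      for (int f = 0; f < Fo; ++f) db[f] += dyb[f + (std::size_t)Fo * j];
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = "cpp_conv_time_fwd")]]
NumericVector cpp_conv_time_fwd(NumericVector x, int Fi, int C, int T, int B,
                                NumericVector W, int Fo, int K, NumericVector bias) {
  return conv_fwd_impl(x, Fi, C, T, B, W, Fo, K, bias, 0);
}

// [[Rcpp::export(name = "cpp_conv_time_bwd")]]
List cpp_conv_time_bwd(NumericVector x, int Fi, int C, int T, int B,
                       NumericVector W, int Fo, int K, NumericVector dy) {
  return conv_bwd_impl(x, Fi, C, T, B, W, Fo, K, dy, 0);
}

// [[Rcpp::export(name = "cpp_conv_space_fwd")]]
NumericVector cpp_conv_space_fwd(NumericVector x, int Fi, int C, int T, int B,
                                 NumericVector W, int Fo, int K, NumericVector bias) {
  return conv_fwd_impl(x, Fi, C, T, B, W, Fo, K, bias, 1);
}

// [[Rcpp::export(name = "cpp_conv_space_bwd")]]
List cpp_conv_space_bwd(NumericVector x, int Fi, int C, int T, int B,
                        NumericVector W, int Fo, int K, NumericVector dy) {
  return conv_bwd_impl(x, Fi, C, T, B, W, Fo, K, dy, 1);
}

// ---------------------------------------------------------------------------
// Depthwise causal 1-D convolution over [E, T, B]; w is [E, K], tap k uses lag k.

// [[Rcpp::export(name = "cpp_dwconv_fwd")]]
NumericVector cpp_dwconv_fwd(NumericVector x, int E, int T, int B,
                             NumericVector w, int K, NumericVector bias) {
  NumericVector y((std::size_t)E * T * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      double* yc = yp + (std::size_t)E * (t + (std::size_t)T * b);
      for (int e = 0; e < E; ++e) yc[e] = bias[e];
      for (int k = 0; k < K && k <= t; ++k) {
        const double* xc = xp + (std::size_t)E * ((t - k) + (std::size_t)T * b);
        const double* wk = w.begin() + (std::size_t)E * k;
        for (int e = 0; e < E; ++e) yc[e] += wk[e] * xc[e];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = "cpp_dwconv_bwd")]]
List cpp_dwconv_bwd(NumericVector x, int E, int T, int B,
                    NumericVector w, int K, NumericVector dy) {
  NumericVector dx((std::size_t)E * T * B);
  NumericVector dw((std::size_t)E * K);
  NumericVector db(E);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const double* dyc = dyp + (std::size_t)E * (t + (std::size_t)T * b);
      for (int e = 0; e < E; ++e) db[e] += dyc[e];
      for (int k = 0; k < K && k <= t; ++k) {
        const double* xc = xp + (std::size_t)E * ((t - k) + (std::size_t)T * b);
        double* dxc = dx.begin() + (std::size_t)E * ((t - k) + (std::size_t)T * b);
        const double* wk = w.begin() + (std::size_t)E * k;
        double* dwk = dw.begin() + (std::size_t)E * k;
        for (int e = 0; e < E; ++e) {
          dxc[e] += wk[e] * dyc[e];
          dwk[e] += xc[e] * dyc[e];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Selective SSM scan with fixed diagonal A = -diag(1..N) and zero-order-hold
// discretization in closed form:
//   A_bar[e,n] = exp(-delta[e] * n) ,  B_bar[e,n] = (1 - A_bar[e,n]) / n * B[n]
//   h_t = A_bar_t (.) h_{t-1} + B_bar_t * u_t ;  y_t = C_t' h_t + D (.) u_t

// [[Rcpp::export(name = "cpp_mamba_scan_fwd")]]
NumericVector cpp_mamba_scan_fwd(NumericVector u, NumericVector delta,
                                 NumericVector Bseq, NumericVector Cseq,
                                 NumericVector Dskip, int E, int N, int T, int B) {
  NumericVector y((std::size_t)E * T * B);
  // h laid out [E x N] with e fastest so the n-loop bodies vectorize over e
  std::vector<double> h((std::size_t)E * N);
  std::vector<double> r(E), rc(E), acc(E);
  std::vector<double> inv_n(N);
  for (int n = 0; n < N; ++n) inv_n[n] = 1.0 / (double)(n + 1);
  for (int b = 0; b < B; ++b) {
    std::fill(h.begin(), h.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const std::size_t seq_off = (std::size_t)E * (t + (std::size_t)T * b);
      const std::size_t bn_off = (std::size_t)N * (t + (std::size_t)T * b);
      const double* Bt = Bseq.begin() + bn_off;
      const double* Ct = Cseq.begin() + bn_off;
      const double* ut = u.begin() + seq_off;
      const double* dt = delta.begin() + seq_off;
      for (int e = 0; e < E; ++e) {
        r[e] = std::exp(-dt[e]);
        rc[e] = 1.0;
        acc[e] = 0.0;
      }
      for (int n = 0; n < N; ++n) {
        double* hn = h.data() + (std::size_t)E * n;
        const double bn = Bt[n] * inv_n[n];
        const double cn = Ct[n];
        for (int e = 0; e < E; ++e) {
          const double ab = rc[e] * r[e];
          rc[e] = ab;
          hn[e] = ab * hn[e] + (1.0 - ab) * bn * ut[e];
          acc[e] += cn * hn[e];
        }
      }
      double* yt = y.begin() + seq_off;
      for (int e = 0; e < E; ++e) yt[e] = acc[e] + Dskip[e] * ut[e];
    }
  }
  return y;
}

// [[Rcpp::export(name = "cpp_mamba_scan_bwd")]]
List cpp_mamba_scan_bwd(NumericVector u, NumericVector delta,
                        NumericVector Bseq, NumericVector Cseq,
                        NumericVector Dskip, int E, int N, int T, int B,
                        NumericVector dy) {
  NumericVector du((std::size_t)E * T * B);
  NumericVector ddelta((std::size_t)E * T * B);
  NumericVector dB((std::size_t)N * T * B);
  NumericVector dC((std::size_t)N * T * B);
  NumericVector dD(E);
  // states for one window, [E x N] per step with e fastest
  std::vector<double> hall((std::size_t)E * N * T);
  std::vector<double> dh((std::size_t)E * N);
  std::vector<double> r(E), rc(E);
  std::vector<double> inv_n(N);
  for (int n = 0; n < N; ++n) inv_n[n] = 1.0 / (double)(n + 1);
  for (int b = 0; b < B; ++b) {
    // forward recompute, storing h_t
    for (int t = 0; t < T; ++t) {
      const std::size_t seq_off = (std::size_t)E * (t + (std::size_t)T * b);
      const double* Bt = Bseq.begin() + (std::size_t)N * (t + (std::size_t)T * b);
      const double* ut = u.begin() + seq_off;
      const double* dt = delta.begin() + seq_off;
      double* ht = hall.data() + (std::size_t)E * N * t;
      const double* hprev = (t > 0) ? hall.data() + (std::size_t)E * N * (t - 1)
                                    : nullptr;
      for (int e = 0; e < E; ++e) { r[e] = std::exp(-dt[e]); rc[e] = 1.0; }
      for (int n = 0; n < N; ++n) {
        double* hn = ht + (std::size_t)E * n;
        const double* hp = hprev ? hprev + (std::size_t)E * n : nullptr;
        const double bn = Bt[n] * inv_n[n];
        for (int e = 0; e < E; ++e) {
          const double ab = rc[e] * r[e];
          rc[e] = ab;
          hn[e] = ab * (hp ? hp[e] : 0.0) + (1.0 - ab) * bn * ut[e];
        }
      }
    }
    // backward
    std::fill(dh.begin(), dh.end(), 0.0);
    for (int t = T - 1; t >= 0; --t) {
      const std::size_t seq_off = (std::size_t)E * (t + (std::size_t)T * b);
      const std::size_t bn_off = (std::size_t)N * (t + (std::size_t)T * b);
      const double* Bt = Bseq.begin() + bn_off;
      const double* Ct = Cseq.begin() + bn_off;
      const double* ut = u.begin() + seq_off;
      const double* dt = delta.begin() + seq_off;
      const double* dyt = dy.begin() + seq_off;
      const double* ht = hall.data() + (std::size_t)E * N * t;
      const double* hprev = (t > 0) ? hall.data() + (std::size_t)E * N * (t - 1)
                                    : nullptr;
      double* dut = du.begin() + seq_off;
      double* ddt = ddelta.begin() + seq_off;
      for (int e = 0; e < E; ++e) {
        r[e] = std::exp(-dt[e]);
        rc[e] = 1.0;
        dD[e] += ut[e] * dyt[e];
        dut[e] = Dskip[e] * dyt[e];
        ddt[e] = 0.0;
      }
      for (int n = 0; n < N; ++n) {
        double* dhn = dh.data() + (std::size_t)E * n;
        const double* hn = ht + (std::size_t)E * n;
        const double* hp = hprev ? hprev + (std::size_t)E * n : nullptr;
        const double bn = Bt[n] * inv_n[n];
        const double cn = Ct[n];
        const double an = -(double)(n + 1);
        double dBn = 0.0, dCn = 0.0;
        for (int e = 0; e < E; ++e) {
          const double ab = rc[e] * r[e];
          rc[e] = ab;
          const double bbar = (1.0 - ab) * bn;
          const double dhen = dhn[e] + cn * dyt[e];
          dCn += hn[e] * dyt[e];
          const double hpe = hp ? hp[e] : 0.0;
          dut[e] += dhen * bbar;
          dBn += dhen * ut[e] * (1.0 - ab) * inv_n[n];
          ddt[e] += (dhen * hpe) * an * ab + (dhen * ut[e]) * ab * Bt[n];
          dhn[e] = dhen * ab;
        }
        dB[bn_off + n] += dBn;
        dC[bn_off + n] += dCn;
      }
    }
  }
  return List::create(_["du"] = du, _["ddelta"] = ddelta, _["dB"] = dB,
                      _["dC"] = dC, _["dD"] = dD);
}

// ---------------------------------------------------------------------------
// RWKV-style WKV recurrence, channel-wise over [D, T, B].
// order = 0 ("rwkv"): state holds history through t-1; the current token
//   enters only through the bonus term.
//     wkv_t = (p_{t-1} + e^{u+k_t} v_t) / (s_{t-1} + e^{u+k_t})
//     s_t = e^{-w} s_{t-1} + e^{k_t} ;  p_t = e^{-w} p_{t-1} + e^{k_t} v_t
// order = 1 ("literal"): the state is updated before use, so the current token
//   is counted both in the state and in the bonus.
// The forward pass runs in log space with a running maximum, so exponents of
// magnitude ~1e2-1e3 remain finite.

// [[Rcpp::export(name = "cpp_wkv_fwd")]]
NumericVector cpp_wkv_fwd(NumericVector k, NumericVector v, NumericVector omega,
                          NumericVector u, int D, int T, int B, int literal) {
  NumericVector out((std::size_t)D * T * B);
  for (int b = 0; b < B; ++b) {
    for (int d = 0; d < D; ++d) {
      double aa = 0.0, bb = 0.0, pp = -1e300;
      const double w = omega[d], ud = u[d];
      for (int t = 0; t < T; ++t) {
        const std::size_t idx = d + (std::size_t)D * (t + (std::size_t)T * b);
        const double kt = k[idx], vt = v[idx];
        if (literal) {  // update state first
          const double wd = pp - w;
          const double q2 = std::max(wd, kt);
          const double e1 = std::exp(wd - q2), e2 = std::exp(kt - q2);
          aa = e1 * aa + e2 * vt;
          bb = e1 * bb + e2;
          pp = q2;
          const double ww = ud + kt;
          const double q = std::max(pp, ww);
          const double f1 = std::exp(pp - q), f2 = std::exp(ww - q);
          out[idx] = (f1 * aa + f2 * vt) / (f1 * bb + f2);
        } else {  // emit with history state, then update
          const double ww = ud + kt;
          const double q = std::max(pp, ww);
          const double f1 = std::exp(pp - q), f2 = std::exp(ww - q);
          out[idx] = (f1 * aa + f2 * vt) / (f1 * bb + f2);
          const double wd = pp - w;
          const double q2 = std::max(wd, kt);
          const double e1 = std::exp(wd - q2), e2 = std::exp(kt - q2);
          aa = e1 * aa + e2 * vt;
          bb = e1 * bb + e2;
          pp = q2;
        }
      }
    }
  }
  return out;
}

// Backward in plain (non-log) arithmetic; valid whenever the naive recurrence
// is finite, which holds throughout training where |k| stays O(1).

// [[Rcpp::export(name = "cpp_wkv_bwd")]]
List cpp_wkv_bwd(NumericVector k, NumericVector v, NumericVector omega,
                 NumericVector u, int D, int T, int B, int literal,
                 NumericVector dwkv) {
  NumericVector dk((std::size_t)D * T * B);
  NumericVector dv((std::size_t)D * T * B);
  NumericVector domega(D);
  NumericVector du(D);
  std::vector<double> S(T), P(T);
  for (int b = 0; b < B; ++b) {
    for (int d = 0; d < D; ++d) {
      const double w = omega[d], ud = u[d];
      const double lam = std::exp(-w);
      double s = 0.0, p = 0.0;
      for (int t = 0; t < T; ++t) {
        const std::size_t idx = d + (std::size_t)D * (t + (std::size_t)T * b);
        const double ek = std::exp(k[idx]);
        s = lam * s + ek;
        p = lam * p + ek * v[idx];
        S[t] = s;
        P[t] = p;
      }
      double dp = 0.0, ds = 0.0, dlam = 0.0;
      for (int t = T - 1; t >= 0; --t) {
        const std::size_t idx = d + (std::size_t)D * (t + (std::size_t)T * b);
        const double kt = k[idx], vt = v[idx];
        const double ek = std::exp(kt);
        const double eb = std::exp(ud + kt);
        const double sprev = (t > 0) ? S[t - 1] : 0.0;
        const double pprev = (t > 0) ? P[t - 1] : 0.0;
        double num, den;
        if (literal) {
          num = P[t] + eb * vt;
          den = S[t] + eb;
        } else {
          num = pprev + eb * vt;
          den = sprev + eb;
        }
        const double g = dwkv[idx];
        const double dnum = g / den;
        const double dden = -(num / den) * g / den;
        if (literal) {
          // adjoint of p_t collects the decayed future plus this step's output
          dp = lam * dp + dnum;
          ds = lam * ds + dden;
          dv[idx] = eb * dnum + ek * dp;
          dk[idx] = eb * (vt * dnum + dden) + ek * (vt * dp + ds);
          du[d] += eb * (vt * dnum + dden);
          dlam += pprev * dp + sprev * ds;
        } else {
          dv[idx] = eb * dnum + ek * dp;
          dk[idx] = eb * (vt * dnum + dden) + ek * (vt * dp + ds);
          du[d] += eb * (vt * dnum + dden);
          dlam += pprev * dp + sprev * ds;
          // adjoint of p_{t-1}, s_{t-1}: decayed future plus this output
          dp = lam * dp + dnum;
          ds = lam * ds + dden;
        }
      }
      domega[d] += -lam * dlam;
    }
  }
  return List::create(_["dk"] = dk, _["dv"] = dv, _["domega"] = domega,
                      _["du"] = du);
}

// ---------------------------------------------------------------------------
// Fused RMSNorm over columns of a [D x M] matrix (single pass, no temporaries).

// [[Rcpp::export(name = "cpp_rmsnorm_fwd")]]
List cpp_rmsnorm_fwd(NumericVector x, NumericVector gain, int D, int M,
                     double eps) {
  NumericVector y((std::size_t)D * M);
  NumericVector r(M);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int j = 0; j < M; ++j) {
    const double* xc = xp + (std::size_t)D * j;
    double s = 0.0;
    for (int d = 0; d < D; ++d) s += xc[d] * xc[d];
    const double rj = std::sqrt(s / D + eps);
    r[j] = rj;
    const double inv = 1.0 / rj;
    double* yc = yp + (std::size_t)D * j;
    for (int d = 0; d < D; ++d) yc[d] = gain[d] * xc[d] * inv;
  }
  return List::create(_["y"] = y, _["r"] = r);
}

// [[Rcpp::export(name = "cpp_rmsnorm_bwd")]]
List cpp_rmsnorm_bwd(NumericVector x, NumericVector r, NumericVector gain,
                     NumericVector dy, int D, int M) {
  NumericVector dx((std::size_t)D * M);
  NumericVector dgain(D);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int j = 0; j < M; ++j) {
    const double* xc = xp + (std::size_t)D * j;
    const double* dyc = dyp + (std::size_t)D * j;
    double* dxc = dx.begin() + (std::size_t)D * j;
    const double inv = 1.0 / r[j];
    double dot = 0.0;
    for (int d = 0; d < D; ++d) dot += dyc[d] * gain[d] * xc[d];
    const double c2 = dot * inv * inv * inv / D;
    for (int d = 0; d < D; ++d) {
      dxc[d] = dyc[d] * gain[d] * inv - xc[d] * c2;
      dgain[d] += dyc[d] * xc[d] * inv;
    }
  }
  return List::create(_["dx"] = dx, _["dgain"] = dgain);
}

// ---------------------------------------------------------------------------
// Fused elementwise activations (single pass, one allocation).

// [[Rcpp::export(name = "cpp_silu")]]
NumericVector cpp_silu(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) {
    yp[i] = xp[i] / (1.0 + std::exp(-xp[i]));
  }
  return y;
}

// dy * d silu(x)/dx, fused.
// [[Rcpp::export(name = "cpp_silu_grad_mul")]]
NumericVector cpp_silu_grad_mul(NumericVector x, NumericVector dy) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = out.begin();
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-xp[i]));
    op[i] = dp[i] * s * (1.0 + xp[i] * (1.0 - s));
  }
  return out;
}

// [[Rcpp::export(name = "cpp_sigmoid")]]
NumericVector cpp_sigmoid(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t n = x.size();
  for (std::size_t i = 0; i < n; ++i) yp[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return y;
}

// softplus(x[e, m] + bias[e]) over an [E x M] matrix, fused.
// [[Rcpp::export(name = "cpp_softplus_bias")]]
NumericVector cpp_softplus_bias(NumericVector x, NumericVector bias, int E,
                                int M) {
  NumericVector y((std::size_t)E * M);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int m = 0; m < M; ++m) {
    const std::size_t off = (std::size_t)E * m;
    for (int e = 0; e < E; ++e) {
      const double v = xp[off + e] + bias[e];
      yp[off + e] = (v > 0 ? v : 0) + std::log1p(std::exp(-std::abs(v)));
    }
  }
  return y;
}

// sigmoid(x[e, m] + bias[e]) * dy, fused (softplus gradient chain).
// [[Rcpp::export(name = "cpp_sigmoid_bias_mul")]]
NumericVector cpp_sigmoid_bias_mul(NumericVector x, NumericVector bias,
                                   NumericVector dy, int E, int M) {
  NumericVector out((std::size_t)E * M);
  const double* xp = x.begin();
  const double* dp = dy.begin();
  double* op = out.begin();
  for (int m = 0; m < M; ++m) {
    const std::size_t off = (std::size_t)E * m;
    for (int e = 0; e < E; ++e) {
      op[off + e] = dp[off + e] /
        (1.0 + std::exp(-(xp[off + e] + bias[e])));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused Mamba stream: causal depthwise conv + SiLU -> parameter projection
// (BLAS) -> softplus step sizes -> selective scan -> SiLU gate, in one call;
// the backward pass mirrors it. Semantically identical to composing the
// exported kernels; fusing removes a dozen large intermediate allocations.

static void dwconv_fwd_core(const double* x, int E, int T, int B,
                            const double* w, int K, const double* bias,
                            double* y) {
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      double* yc = y + (std::size_t)E * (t + (std::size_t)T * b);
      for (int e = 0; e < E; ++e) yc[e] = bias[e];
      for (int k = 0; k < K && k <= t; ++k) {
        const double* xc = x + (std::size_t)E * ((t - k) + (std::size_t)T * b);
        const double* wk = w + (std::size_t)E * k;
        for (int e = 0; e < E; ++e) yc[e] += wk[e] * xc[e];
      }
    }
  }
}

static void mamba_scan_fwd_core(const double* u, const double* delta,
                                const double* Bseq, const double* Cseq,
                                const double* Dskip, int E, int N, int T,
                                int B, double* y) {
  std::vector<double> h((std::size_t)E * N);
  std::vector<double> r(E), rc(E), acc(E);
  std::vector<double> inv_n(N);
  for (int n = 0; n < N; ++n) inv_n[n] = 1.0 / (double)(n + 1);
  for (int b = 0; b < B; ++b) {
    std::fill(h.begin(), h.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const std::size_t seq_off = (std::size_t)E * (t + (std::size_t)T * b);
      const std::size_t bn_off = (std::size_t)N * (t + (std::size_t)T * b);
      const double* Bt = Bseq + bn_off;
      const double* Ct = Cseq + bn_off;
      const double* ut = u + seq_off;
      const double* dt = delta + seq_off;
      for (int e = 0; e < E; ++e) {
        r[e] = std::exp(-dt[e]);
        rc[e] = 1.0;
        acc[e] = 0.0;
      }
      for (int n = 0; n < N; ++n) {
        double* hn = h.data() + (std::size_t)E * n;
        const double bn = Bt[n] * inv_n[n];
        const double cn = Ct[n];
        for (int e = 0; e < E; ++e) {
          const double ab = rc[e] * r[e];
          rc[e] = ab;
          hn[e] = ab * hn[e] + (1.0 - ab) * bn * ut[e];
          acc[e] += cn * hn[e];
        }
      }
      double* yt = y + seq_off;
      for (int e = 0; e < E; ++e) yt[e] = acc[e] + Dskip[e] * ut[e];
    }
  }
}

// [[Rcpp::export(name = "cpp_mamba_stream_fwd")]]
List cpp_mamba_stream_fwd(NumericVector u, NumericVector conv_w,
                          NumericVector conv_b, NumericVector Wx,
                          NumericVector delta_bias, NumericVector Wg,
                          NumericVector Dskip, int E, int N, int K, int T,
                          int B) {
  const std::size_t M = (std::size_t)T * B;
  const int P = E + 2 * N;
  NumericVector cv(E * M), a(E * M), draw(E * M), delta(E * M);
  NumericVector Bs((std::size_t)N * M), Cs((std::size_t)N * M);
  NumericVector yscan(E * M), gpre(E * M), out(E * M);
  dwconv_fwd_core(u.begin(), E, T, B, conv_w.begin(), K, conv_b.begin(),
                  cv.begin());
  for (std::size_t i = 0; i < E * M; ++i) {
    a[i] = cv[i] / (1.0 + std::exp(-cv[i]));
  }
  std::vector<double> pbc((std::size_t)P * M);
  dgemm_nn(P, (int)M, E, 1.0, Wx.begin(), P, a.begin(), E, 0.0, pbc.data(), P);
  for (std::size_t m = 0; m < M; ++m) {
    const double* col = pbc.data() + (std::size_t)P * m;
    double* dr = draw.begin() + (std::size_t)E * m;
    double* de = delta.begin() + (std::size_t)E * m;
    for (int e = 0; e < E; ++e) {
      dr[e] = col[e];
      const double v = col[e] + delta_bias[e];
      de[e] = (v > 0 ? v : 0) + std::log1p(std::exp(-std::abs(v)));
    }
    double* bs = Bs.begin() + (std::size_t)N * m;
    double* cs = Cs.begin() + (std::size_t)N * m;
    for (int n = 0; n < N; ++n) {
      bs[n] = col[E + n];
      cs[n] = col[E + N + n];
    }
  }
  mamba_scan_fwd_core(a.begin(), delta.begin(), Bs.begin(), Cs.begin(),
                      Dskip.begin(), E, N, T, B, yscan.begin());
  dgemm_nn(E, (int)M, E, 1.0, Wg.begin(), E, u.begin(), E, 0.0, gpre.begin(),
           E);
  for (std::size_t i = 0; i < E * M; ++i) {
    const double g = gpre[i] / (1.0 + std::exp(-gpre[i]));
    out[i] = yscan[i] * g;
  }
  return List::create(_["out"] = out, _["cv"] = cv, _["a"] = a,
                      _["draw"] = draw, _["delta"] = delta, _["Bs"] = Bs,
                      _["Cs"] = Cs, _["yscan"] = yscan, _["gpre"] = gpre);
}

// [[Rcpp::export(name = "cpp_mamba_stream_bwd")]]
List cpp_mamba_stream_bwd(NumericVector u, NumericVector conv_w,
                          NumericVector Wx, NumericVector delta_bias,
                          NumericVector Wg, NumericVector Dskip,
                          NumericVector cv, NumericVector a,
                          NumericVector draw, NumericVector delta,
                          NumericVector Bs, NumericVector Cs,
                          NumericVector yscan, NumericVector gpre,
                          int E, int N, int K, int T, int B,
                          NumericVector dout) {
  const std::size_t M = (std::size_t)T * B;
  const int P = E + 2 * N;
  NumericVector du(E * M), dWx((std::size_t)P * E), dWg((std::size_t)E * E);
  NumericVector dconv_w((std::size_t)E * K), dconv_b(E), ddelta_bias(E),
      dDskip(E);
  // gate path
  std::vector<double> dy(E * M), dgpre(E * M);
  for (std::size_t i = 0; i < E * M; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-gpre[i]));
    const double g = gpre[i] * s;
    dy[i] = dout[i] * g;
    dgpre[i] = dout[i] * yscan[i] * s * (1.0 + gpre[i] * (1.0 - s));
  }
  dgemm_nt(E, E, (int)M, 1.0, dgpre.data(), E, u.begin(), E, 0.0, dWg.begin(),
           E);
  dgemm_tn(E, (int)M, E, 1.0, Wg.begin(), E, dgpre.data(), E, 0.0, du.begin(),
           E);
  // scan backward (recomputes states per window)
  std::vector<double> da(E * M), dpbc((std::size_t)P * M);
  {
    std::vector<double> hall((std::size_t)E * N * T);
    std::vector<double> dh((std::size_t)E * N);
    std::vector<double> r(E), rc(E);
    std::vector<double> inv_n(N);
    for (int n = 0; n < N; ++n) inv_n[n] = 1.0 / (double)(n + 1);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < T; ++t) {
        const std::size_t seq_off = (std::size_t)E * (t + (std::size_t)T * b);
        const double* Bt = Bs.begin() + (std::size_t)N * (t + (std::size_t)T * b);
        const double* ut = a.begin() + seq_off;
        const double* dt = delta.begin() + seq_off;
        double* ht = hall.data() + (std::size_t)E * N * t;
        const double* hprev =
            (t > 0) ? hall.data() + (std::size_t)E * N * (t - 1) : nullptr;
        for (int e = 0; e < E; ++e) { r[e] = std::exp(-dt[e]); rc[e] = 1.0; }
        for (int n = 0; n < N; ++n) {
          double* hn = ht + (std::size_t)E * n;
          const double* hp = hprev ? hprev + (std::size_t)E * n : nullptr;
          const double bn = Bt[n] * inv_n[n];
          for (int e = 0; e < E; ++e) {
            const double ab = rc[e] * r[e];
            rc[e] = ab;
            hn[e] = ab * (hp ? hp[e] : 0.0) + (1.0 - ab) * bn * ut[e];
          }
        }
      }
      std::fill(dh.begin(), dh.end(), 0.0);
      for (int t = T - 1; t >= 0; --t) {
        const std::size_t seq_off = (std::size_t)E * (t + (std::size_t)T * b);
        const std::size_t bn_off = (std::size_t)N * (t + (std::size_t)T * b);
        const double* Bt = Bs.begin() + bn_off;
        const double* Ct = Cs.begin() + bn_off;
        const double* ut = a.begin() + seq_off;
        const double* dt = delta.begin() + seq_off;
        const double* dyt = dy.data() + seq_off;
        const double* ht = hall.data() + (std::size_t)E * N * t;
        const double* hprev =
            (t > 0) ? hall.data() + (std::size_t)E * N * (t - 1) : nullptr;
        double* dut = da.data() + seq_off;
        double* ddt = dpbc.data() + (std::size_t)P * 0; // filled below per col
        double* dcol = dpbc.data() + (std::size_t)P * (t + (std::size_t)T * b);
        for (int e = 0; e < E; ++e) {
          r[e] = std::exp(-dt[e]);
          rc[e] = 1.0;
          dDskip[e] += ut[e] * dyt[e];
          dut[e] = Dskip[e] * dyt[e];
          dcol[e] = 0.0;
        }
        (void)ddt;
        for (int n = 0; n < N; ++n) {
          double* dhn = dh.data() + (std::size_t)E * n;
          const double* hn = ht + (std::size_t)E * n;
          const double* hp = hprev ? hprev + (std::size_t)E * n : nullptr;
          const double bn = Bt[n] * inv_n[n];
          const double cn = Ct[n];
          const double an = -(double)(n + 1);
          double dBn = 0.0, dCn = 0.0;
          for (int e = 0; e < E; ++e) {
            const double ab = rc[e] * r[e];
            rc[e] = ab;
            const double bbar = (1.0 - ab) * bn;
            const double dhen = dhn[e] + cn * dyt[e];
            dCn += hn[e] * dyt[e];
            const double hpe = hp ? hp[e] : 0.0;
            dut[e] += dhen * bbar;
            dBn += dhen * ut[e] * (1.0 - ab) * inv_n[n];
            dcol[e] += (dhen * hpe) * an * ab + (dhen * ut[e]) * ab * Bt[n];
            dhn[e] = dhen * ab;
          }
          dcol[E + n] = dBn;
          dcol[E + N + n] = dCn;
        }
      }
    }
  }
  // chain softplus on the delta rows of dpbc, accumulate its bias gradient
  for (std::size_t m = 0; m < M; ++m) {
    double* dcol = dpbc.data() + (std::size_t)P * m;
    const double* dr = draw.begin() + (std::size_t)E * m;
    for (int e = 0; e < E; ++e) {
      dcol[e] /= (1.0 + std::exp(-(dr[e] + delta_bias[e])));
      ddelta_bias[e] += dcol[e];
    }
  }
  // parameter projection backward
  dgemm_nt(P, E, (int)M, 1.0, dpbc.data(), P, a.begin(), E, 0.0, dWx.begin(),
           P);
  dgemm_tn(E, (int)M, P, 1.0, Wx.begin(), P, dpbc.data(), P, 1.0, da.data(),
           E);
  // conv + SiLU backward
  std::vector<double> dcv(E * M);
  for (std::size_t i = 0; i < E * M; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-cv[i]));
    dcv[i] = da[i] * s * (1.0 + cv[i] * (1.0 - s));
  }
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      const double* dyc = dcv.data() + (std::size_t)E * (t + (std::size_t)T * b);
      for (int e = 0; e < E; ++e) dconv_b[e] += dyc[e];
      for (int k = 0; k < K && k <= t; ++k) {
        const double* xc =
            u.begin() + (std::size_t)E * ((t - k) + (std::size_t)T * b);
        double* duc = du.begin() + (std::size_t)E * ((t - k) + (std::size_t)T * b);
        const double* wk = conv_w.begin() + (std::size_t)E * k;
        double* dwk = dconv_w.begin() + (std::size_t)E * k;
        for (int e = 0; e < E; ++e) {
          duc[e] += wk[e] * dyc[e];
          dwk[e] += xc[e] * dyc[e];
        }
      }
    }
  }
  return List::create(_["du"] = du, _["dconv_w"] = dconv_w,
                      _["dconv_b"] = dconv_b, _["dWx"] = dWx,
                      _["ddelta_bias"] = ddelta_bias, _["dWg"] = dWg,
                      _["dDskip"] = dDskip);
}
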