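#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Array layout convention throughout: feature maps are R arrays with
// dim (H, W, C, N), column-major. Patch columns are ordered (ky, kx, c);
// output rows are ordered (oy, ox, n).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  const int rows = oh * ow * N, cols = kh * kw * C;
  NumericMatrix out(rows, cols);
  const double *xp = x.begin();
  double *op = out.begin();
  const long planeHW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const long col = ky + (long)kh * kx + (long)kh * kw * c;
        double *ocol = op + col * rows;
        for (int n = 0; n < N; ++n) {
          const double *xplane = xp + ((long)n * C + c) * planeHW;
          for (int ox = 0; ox < ow; ++ox) {
            const int ix = ox * stride + kx - pad;
            long r = (long)n * oh * ow + (long)ox * oh;
            if (ix < 0 || ix >= W) {
              for (int oy = 0; oy < oh; ++oy) ocol[r + oy] = 0.0;
              continue;
            }
            const double *xcol = xplane + (long)ix * H;
            for (int oy = 0; oy < oh; ++oy) {
              const int iy = oy * stride + ky - pad;
              ocol[r + oy] = (iy < 0 || iy >= H) ? 0.0 : xcol[iy];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  NumericVector x((long)H * W * C * N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  const long rows = (long)oh * ow * N;
  const long planeHW = (long)H * W;
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const long col = ky + (long)kh * kx + (long)kh * kw * c;
        const double *ccol = cp + col * rows;
        for (int n = 0; n < N; ++n) {
          double *xplane = xp + ((long)n * C + c) * planeHW;
          for (int ox = 0; ox < ow; ++ox) {
            const int ix = ox * stride + kx - pad;
            if (ix < 0 || ix >= W) continue;
            long r = (long)n * oh * ow + (long)ox * oh;
            double *xcol = xplane + (long)ix * H;
            for (int oy = 0; oy < oh; ++oy) {
              const int iy = oy * stride + ky - pad;
              if (iy >= 0 && iy < H) xcol[iy] += ccol[r + oy];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Depthwise k x k convolution, stride 1, zero padding (k-1)/2.
// w has dim (k, k, C); b length C.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int H, int W, int C, int N,
                             NumericVector w, NumericVector b, int k) {
  const int pad = (k - 1) / 2;
  NumericVector y((long)H * W * C * N);
  const double *xp = x.begin(), *wp = w.begin(), *bp = b.begin();
  double *yp = y.begin();
  const long planeHW = (long)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xpl = xp + ((long)n * C + c) * planeHW;
      double *ypl = yp + ((long)n * C + c) * planeHW;
      const double *wc = wp + (long)k * k * c;
      for (int wx = 0; wx < W; ++wx) {
        for (int hy = 0; hy < H; ++hy) {
          double acc = bp[c];
          for (int kx = 0; kx < k; ++kx) {
            const int ix = wx + kx - pad;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = hy + ky - pad;
              if (iy < 0 || iy >= H) continue;
              acc += xpl[(long)ix * H + iy] * wc[ky + k * kx];
            }
          }
          ypl[(long)wx * H + hy] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector g, int H, int W, int C,
                    int N, NumericVector w, int k) {
  const int pad = (k - 1) / 2;
  NumericVector gx((long)H * W * C * N);
  NumericVector gw((long)k * k * C);
  NumericVector gb(C);
  const double *xp = x.begin(), *gp = g.begin(), *wp = w.begin();
  double *gxp = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();
  const long planeHW = (long)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xpl = xp + ((long)n * C + c) * planeHW;
      const double *gpl = gp + ((long)n * C + c) * planeHW;
      double *gxpl = gxp + ((long)n * C + c) * planeHW;
      const double *wc = wp + (long)k * k * c;
      double *gwc = gwp + (long)k * k * c;
      for (int wx = 0; wx < W; ++wx) {
        for (int hy = 0; hy < H; ++hy) {
          const double gv = gpl[(long)wx * H + hy];
          gbp[c] += gv;
          for (int kx = 0; kx < k; ++kx) {
            const int ix = wx + kx - pad;
            if (ix < 0 || ix >= W) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = hy + ky - pad;
              if (iy < 0 || iy >= H) continue;
              gxpl[(long)ix * H + iy] += gv * wc[ky + k * kx];
              gwc[ky + k * kx] += gv * xpl[(long)ix * H + iy];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static inline double phi_zoh(double z) {
  // (exp(z) - 1) / z, continuous through z = 0
  if (std::fabs(z) < 1e-12) return 1.0;
  return std::expm1(z) / z;
}

static inline double dphi_zoh(double z) {
  // derivative of phi: (exp(z)*(z-1) + 1) / z^2, series near 0
  if (std::fabs(z) < 1e-5) return 0.5 + z / 3.0 + z * z / 8.0;
  return (std::exp(z) * (z - 1.0) + 1.0) / (z * z);
}

// Selective-scan forward for one sequence.
// u: L x D input; delta: L x D (positive step sizes); B, C: L x n_state
// (input-dependent); A: D x n_state (continuous, typically negative);
// Dskip: length D. ZOH: abar = exp(delta*A); bbar = phi(delta*A)*delta*B.
// h[d,s]_t = abar*h_{t-1} + bbar*u[t,d]; y[t,d] = sum_s C[t,s]*h[d,s] + Dskip[d]*u[t,d]
// [[Rcpp::export]]
List ssm_scan_fwd_cpp(NumericMatrix u, NumericMatrix delta, NumericMatrix B,
                      NumericMatrix C, NumericMatrix A, NumericVector Dskip) {
  const int L = u.nrow(), D = u.ncol(), S = A.ncol();
  NumericMatrix y(L, D);
  NumericVector hall((long)L * D * S), asave((long)L * D * S),
      psave((long)L * D * S);
  std::vector<double> h((size_t)D * S, 0.0);
  double *hp = h.data();
  for (int t = 0; t < L; ++t) {
    for (int d = 0; d < D; ++d) {
      const double dt = delta(t, d), ut = u(t, d);
      double acc = 0.0;
      double *hd = hp + (size_t)d * S;
      for (int s = 0; s < S; ++s) {
        const long idx = (long)t + (long)L * (d + (long)D * s);
        const double z = dt * A(d, s);
        const double abar = std::exp(z);
        const double ph = phi_zoh(z);
        const double bbar = ph * dt * B(t, s);
        hd[s] = abar * hd[s] + bbar * ut;
        acc += C(t, s) * hd[s];
        hall[idx] = hd[s];
        asave[idx] = abar;
        psave[idx] = ph;
      }
      y(t, d) = acc + Dskip[d] * ut;
    }
  }
  hall.attr("dim") = IntegerVector::create(L, D, S);
  return List::create(_["y"] = y, _["h"] = hall, _["abar"] = asave,
                      _["phi"] = psave);
}

// [[Rcpp::export]]
List ssm_scan_bwd_cpp(NumericMatrix u, NumericMatrix delta, NumericMatrix B,
                      NumericMatrix C, NumericMatrix A, NumericVector Dskip,
                      NumericVector hall, NumericVector asave,
                      NumericVector psave, NumericMatrix gy) {
  const int L = u.nrow(), D = u.ncol(), S = A.ncol();
  NumericMatrix gu(L, D), gdelta(L, D), gB(L, S), gC(L, S), gA(D, S);
  NumericVector gD(D);
  std::vector<double> gh((size_t)D * S, 0.0);
  const double *hv = hall.begin(), *av = asave.begin(), *pv = psave.begin();
  for (int t = L - 1; t >= 0; --t) {
    for (int d = 0; d < D; ++d) {
      const double gyv = gy(t, d), ut = u(t, d), dt = delta(t, d);
      gD[d] += gyv * ut;
      gu(t, d) += gyv * Dskip[d];
      double *ghd = gh.data() + (size_t)d * S;
      for (int s = 0; s < S; ++s) {
        const long idx = (long)t + (long)L * (d + (long)D * s);
        const double ht = hv[idx];
        gC(t, s) += gyv * ht;
        double g = ghd[s] + gyv * C(t, s);
        const double z = dt * A(d, s);
        const double abar = av[idx];
        const double ph = pv[idx];
        const double hprev =
            (t > 0) ? hv[(long)(t - 1) + (long)L * (d + (long)D * s)] : 0.0;
        // h = abar*hprev + phi(z)*dt*B*u
        const double Bt = B(t, s);
        gu(t, d) += g * ph * dt * Bt;
        gB(t, s) += g * ph * dt * ut;
        // dz contributions (z = dt * A[d,s]); dphi = (abar - phi)/z
        const double dphi =
            (std::fabs(z) < 1e-5) ? dphi_zoh(z) : (abar - ph) / z;
        const double dz = g * (hprev * abar + dphi * dt * Bt * ut);
        // explicit dt dependence in bbar
        const double ddt = g * ph * Bt * ut + dz * A(d, s);
        gdelta(t, d) += ddt;
        gA(d, s) += dz * dt;
        ghd[s] = g * abar;  // propagate to h_{t-1}
      }
    }
  }
  return List::create(_["gu"] = gu, _["gdelta"] = gdelta, _["gB"] = gB,
                      _["gC"] = gC, _["gA"] = gA, _["gD"] = gD);
}

// Stacked-batch selective scan: rows hold N independent length-L sequences
// (sample-contiguous blocks). u, delta: (L*N) x D; B, C: (L*N) x S.
// Saved state uses (S, D, t) layout for contiguous access; phi is
// reconstructed from abar in the backward pass.
// [[Rcpp::export]]
List ssm_scan_fwd_batch_cpp(NumericMatrix u, NumericMatrix delta,
                            NumericMatrix B, NumericMatrix C, NumericMatrix A,
                            NumericVector Dskip, int N) {
  const int LN = u.nrow(), D = u.ncol(), S = A.ncol();
  const int L = LN / N;
  NumericMatrix y(LN, D);
  NumericVector hall((long)LN * D * S), asave((long)LN * D * S);
  std::vector<double> h((size_t)D * S);
  std::vector<double> Arow((size_t)D * S);  // A in (s,d) layout
  for (int d = 0; d < D; ++d)
    for (int s = 0; s < S; ++s) Arow[(size_t)d * S + s] = A(d, s);
  double *hv = hall.begin(), *av = asave.begin();
  for (int n = 0; n < N; ++n) {
    std::fill(h.begin(), h.end(), 0.0);
    for (int tt = 0; tt < L; ++tt) {
      const int t = n * L + tt;
      double *ht = hv + (long)t * D * S;
      double *at = av + (long)t * D * S;
      for (int d = 0; d < D; ++d) {
        const double dt = delta(t, d), ut = u(t, d);
        double acc = 0.0;
        double *hd = h.data() + (size_t)d * S;
        double *hts = ht + (long)d * S;
        double *ats = at + (long)d * S;
        const double *Ad = Arow.data() + (size_t)d * S;
        for (int s = 0; s < S; ++s) {
          const double z = dt * Ad[s];
          const double abar = std::exp(z);
          const double ph = (std::fabs(z) < 1e-6) ? 1.0 + 0.5 * z
                                                  : (abar - 1.0) / z;
          hd[s] = abar * hd[s] + ph * dt * B(t, s) * ut;
          acc += C(t, s) * hd[s];
          hts[s] = hd[s];
          ats[s] = abar;
        }
        y(t, d) = acc + Dskip[d] * ut;
      }
    }
  }
  return List::create(_["y"] = y, _["h"] = hall, _["abar"] = asave);
}

// [[Rcpp::export]]
List ssm_scan_bwd_batch_cpp(NumericMatrix u, NumericMatrix delta,
                            NumericMatrix B, NumericMatrix C, NumericMatrix A,
                            NumericVector Dskip, NumericVector hall,
                            NumericVector asave, NumericMatrix gy, int N) {
  const int LN = u.nrow(), D = u.ncol(), S = A.ncol();
  const int L = LN / N;
  NumericMatrix gu(LN, D), gdelta(LN, D), gB(LN, S), gC(LN, S), gA(D, S);
  NumericVector gD(D);
  std::vector<double> gh((size_t)D * S);
  std::vector<double> Arow((size_t)D * S), gArow((size_t)D * S, 0.0);
  for (int d = 0; d < D; ++d)
    for (int s = 0; s < S; ++s) Arow[(size_t)d * S + s] = A(d, s);
  std::vector<double> gBrow(S), gCrow(S), Brow(S), Crow(S);
  const double *hv = hall.begin(), *av = asave.begin();
  for (int n = 0; n < N; ++n) {
    std::fill(gh.begin(), gh.end(), 0.0);
    for (int tt = L - 1; tt >= 0; --tt) {
      const int t = n * L + tt;
      const double *ht = hv + (long)t * D * S;
      const double *htp = ht - (long)D * S;  // previous token (same sample)
      const double *at = av + (long)t * D * S;
      for (int s = 0; s < S; ++s) {
        gBrow[s] = 0.0; gCrow[s] = 0.0;
        Brow[s] = B(t, s); Crow[s] = C(t, s);
      }
      for (int d = 0; d < D; ++d) {
        const double gyv = gy(t, d), ut = u(t, d), dt = delta(t, d);
        gD[d] += gyv * ut;
        double gut = gyv * Dskip[d];
        double gdt = 0.0;
        double *ghd = gh.data() + (size_t)d * S;
        const double *hts = ht + (long)d * S;
        const double *hps = htp + (long)d * S;
        const double *ats = at + (long)d * S;
        const double *Ad = Arow.data() + (size_t)d * S;
        double *gAd = gArow.data() + (size_t)d * S;
        for (int s = 0; s < S; ++s) {
          gCrow[s] += gyv * hts[s];
          double g = ghd[s] + gyv * Crow[s];
          const double z = dt * Ad[s];
          const double abar = ats[s];
          const double ph = (std::fabs(z) < 1e-6) ? 1.0 + 0.5 * z
                                                  : (abar - 1.0) / z;
          const double hprev = (tt > 0) ? hps[s] : 0.0;
          const double Bt = Brow[s];
          gut += g * ph * dt * Bt;
          gBrow[s] += g * ph * dt * ut;
          const double dphi =
              (std::fabs(z) < 1e-5) ? dphi_zoh(z) : (abar - ph) / z;
          const double dz = g * (hprev * abar + dphi * dt * Bt * ut);
          gdt += g * ph * Bt * ut + dz * Ad[s];
          gAd[s] += dz * dt;
          ghd[s] = g * abar;
        }
        gu(t, d) = gut;
        gdelta(t, d) = gdt;
      }
      for (int s = 0; s < S; ++s) {
        gB(t, s) = gBrow[s];
        gC(t, s) = gCrow[s];
      }
    }
  }
  for (int d = 0; d < D; ++d)
    for (int s = 0; s < S; ++s) gA(d, s) = gArow[(size_t)d * S + s];
  return List::create(_["gu"] = gu, _["gdelta"] = gdelta, _["gB"] = gB,
                      _["gC"] = gC, _["gA"] = gA, _["gD"] = gD);
}

// Group-norm forward over (H,W,C,N) with per-channel affine.
// [[Rcpp::export]]
List groupnorm_fwd_cpp(NumericVector x, int H, int W, int C, int N, int G,
                       NumericVector gamma, NumericVector beta, double eps) {
  const long HW = (long)H * W;
  const int cg = C / G;
  const long gl = HW * cg;  // elements per (group, sample)
  NumericVector v(x.size()), xhat(x.size());
  NumericVector sdv(G * N), muv(G * N);
  const double *xp = x.begin();
  double *vp = v.begin(), *xh = xhat.begin();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < G; ++g) {
      const long off = ((long)n * C + (long)g * cg) * HW;
      double s = 0, s2 = 0;
      for (long i = 0; i < gl; ++i) { const double val = xp[off + i]; s += val; s2 += val * val; }
      const double mu = s / gl;
      const double var = s2 / gl - mu * mu;
      const double sd = std::sqrt(var > 0 ? var + eps : eps);
      muv[n * G + g] = mu; sdv[n * G + g] = sd;
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[g * cg + c], be = beta[g * cg + c];
        const long o2 = off + (long)c * HW;
        for (long i = 0; i < HW; ++i) {
          const double xn = (xp[o2 + i] - mu) / sd;
          xh[o2 + i] = xn;
          vp[o2 + i] = xn * ga + be;
        }
      }
    }
  }
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["v"] = v, _["xhat"] = xhat, _["sd"] = sdv);
}

// [[Rcpp::export]]
List groupnorm_bwd_cpp(NumericVector g, NumericVector xhat, NumericVector sdv,
                       int H, int W, int C, int N, int G,
                       NumericVector gamma) {
  const long HW = (long)H * W;
  const int cg = C / G;
  const long gl = HW * cg;
  NumericVector gx(g.size()), ggam(C), gbet(C);
  const double *gp = g.begin(), *xh = xhat.begin();
  for (int n = 0; n < N; ++n) {
    for (int gr = 0; gr < G; ++gr) {
      const long off = ((long)n * C + (long)gr * cg) * HW;
      const double sd = sdv[n * G + gr];
      double m1 = 0, m2 = 0;
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[gr * cg + c];
        const long o2 = off + (long)c * HW;
        double sg = 0, sgx = 0;
        for (long i = 0; i < HW; ++i) {
          const double gv = gp[o2 + i];
          sg += gv;
          sgx += gv * xh[o2 + i];
          m1 += gv * ga;
          m2 += gv * ga * xh[o2 + i];
        }
        gbet[gr * cg + c] += sg;
        ggam[gr * cg + c] += sgx;
      }
      m1 /= gl; m2 /= gl;
      for (int c = 0; c < cg; ++c) {
        const double ga = gamma[gr * cg + c];
        const long o2 = off + (long)c * HW;
        for (long i = 0; i < HW; ++i) {
          gx[o2 + i] = (gp[o2 + i] * ga - m1 - xh[o2 + i] * m2) / sd;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["gx"] = gx, _["ggamma"] = ggam, _["gbeta"] = gbet);
}

// Fused single-head attention over N stacked sequences. Q,K,V: (L*N) x dh.
// Softmax rows are cached transposed: Ssave is L x (L*N), column i holding
// the attention row of token i.
// [[Rcpp::export]]
List attn_fwd_cpp(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                  int N, double scale) {
  const int LN = Q.nrow(), dh = Q.ncol();
  const int L = LN / N;
  NumericMatrix O(LN, dh), S(L, LN);
  std::vector<double> row(L);
  const double *q = Q.begin(), *k = K.begin(), *v = V.begin();
  double *sp = S.begin(), *op = O.begin();
  for (int n = 0; n < N; ++n) {
    const int off = n * L;
    for (int i = 0; i < L; ++i) {
      const int gi = off + i;
      // scores row
      for (int j = 0; j < L; ++j) row[j] = 0.0;
      for (int d = 0; d < dh; ++d) {
        const double qd = q[gi + (long)LN * d] * scale;
        const double *kd = k + off + (long)LN * d;
        for (int j = 0; j < L; ++j) row[j] += qd * kd[j];
      }
      double mx = row[0];
      for (int j = 1; j < L; ++j) if (row[j] > mx) mx = row[j];
      double sum = 0.0;
      for (int j = 0; j < L; ++j) { row[j] = std::exp(row[j] - mx); sum += row[j]; }
      const double inv = 1.0 / sum;
      double *scol = sp + (long)gi * L;
      for (int j = 0; j < L; ++j) scol[j] = row[j] * inv;
      for (int d = 0; d < dh; ++d) {
        const double *vd = v + off + (long)LN * d;
        double acc = 0.0;
        for (int j = 0; j < L; ++j) acc += scol[j] * vd[j];
        op[gi + (long)LN * d] = acc;
      }
    }
  }
  return List::create(_["out"] = O, _["soft"] = S);
}

// [[Rcpp::export]]
List attn_bwd_cpp(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                  NumericMatrix S, NumericMatrix gO, int N, double scale) {
  const int LN = Q.nrow(), dh = Q.ncol();
  const int L = LN / N;
  NumericMatrix gQ(LN, dh), gK(LN, dh), gV(LN, dh);
  std::vector<double> gs(L), gz(L);
  const double *q = Q.begin(), *k = K.begin(), *v = V.begin(),
               *sp = S.begin(), *go = gO.begin();
  double *gq = gQ.begin(), *gk = gK.begin(), *gv = gV.begin();
  for (int n = 0; n < N; ++n) {
    const int off = n * L;
    for (int i = 0; i < L; ++i) {
      const int gi = off + i;
      const double *scol = sp + (long)gi * L;
      // gS row = gO_i . V^T ; also accumulate gV += S_i^T gO_i
      for (int j = 0; j < L; ++j) gs[j] = 0.0;
      for (int d = 0; d < dh; ++d) {
        const double god = go[gi + (long)LN * d];
        const double *vd = v + off + (long)LN * d;
        double *gvd = gv + off + (long)LN * d;
        for (int j = 0; j < L; ++j) {
          gs[j] += god * vd[j];
          gvd[j] += god * scol[j];
        }
      }
      // softmax backward on the row
      double dot = 0.0;
      for (int j = 0; j < L; ++j) dot += gs[j] * scol[j];
      for (int j = 0; j < L; ++j) gz[j] = (gs[j] - dot) * scol[j] * scale;
      // gQ_i += gz . K ; gK += gz^T outer Q_i
      for (int d = 0; d < dh; ++d) {
        const double *kd = k + off + (long)LN * d;
        const double qd = q[gi + (long)LN * d];
        double *gkd = gk + off + (long)LN * d;
        double acc = 0.0;
        for (int j = 0; j < L; ++j) {
          acc += gz[j] * kd[j];
          gkd[j] += gz[j] * qd;
        }
        gq[gi + (long)LN * d] = acc;
      }
    }
  }
  return List::create(_["gQ"] = gQ, _["gK"] = gK, _["gV"] = gV);
}

// Fused row layer norm over tokens x channels, per-channel affine.
// [[Rcpp::export]]
List layernorm_fwd_cpp(NumericMatrix x, NumericVector gamma,
                       NumericVector beta, double eps) {
  const int T = x.nrow(), C = x.ncol();
  NumericMatrix v(T, C), xhat(T, C);
  NumericVector sdv(T);
  const double *xp = x.begin();
  double *vp = v.begin(), *xh = xhat.begin();
  for (int i = 0; i < T; ++i) {
    double s = 0, s2 = 0;
    for (int c = 0; c < C; ++c) { const double val = xp[i + (long)T * c]; s += val; s2 += val * val; }
    const double mu = s / C;
    double var = s2 / C - mu * mu;
    if (var < 0) var = 0;
    const double sd = std::sqrt(var + eps);
    sdv[i] = sd;
    for (int c = 0; c < C; ++c) {
      const double xn = (xp[i + (long)T * c] - mu) / sd;
      xh[i + (long)T * c] = xn;
      vp[i + (long)T * c] = xn * gamma[c] + beta[c];
    }
  }
  return List::create(_["v"] = v, _["xhat"] = xhat, _["sd"] = sdv);
}

// [[Rcpp::export]]
List layernorm_bwd_cpp(NumericMatrix g, NumericMatrix xhat, NumericVector sdv,
                       NumericVector gamma) {
  const int T = g.nrow(), C = g.ncol();
  NumericMatrix gx(T, C);
  NumericVector ggam(C), gbet(C);
  const double *gp = g.begin(), *xh = xhat.begin();
  double *gxp = gx.begin();
  for (int i = 0; i < T; ++i) {
    double m1 = 0, m2 = 0;
    for (int c = 0; c < C; ++c) {
      const double dxh = gp[i + (long)T * c] * gamma[c];
      m1 += dxh;
      m2 += dxh * xh[i + (long)T * c];
      ggam[c] += gp[i + (long)T * c] * xh[i + (long)T * c];
      gbet[c] += gp[i + (long)T * c];
    }
    m1 /= C; m2 /= C;
    const double inv = 1.0 / sdv[i];
    for (int c = 0; c < C; ++c) {
      gxp[i + (long)T * c] =
          (gp[i + (long)T * c] * gamma[c] - m1 - xh[i + (long)T * c] * m2) * inv;
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggam, _["gbeta"] = gbet);
}

// [[Rcpp::export]]
List silu_fwd_cpp(NumericVector x) {
  NumericVector v(x.size()), sg(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    sg[i] = s;
    v[i] = x[i] * s;
  }
  v.attr("dim") = x.attr("dim");
  return List::create(_["v"] = v, _["s"] = sg);
}

// [[Rcpp::export]]
NumericVector silu_bwd_cpp(NumericVector g, NumericVector x, NumericVector s) {
  NumericVector gx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) {
    gx[i] = g[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  }
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// [[Rcpp::export]]
List gelu_fwd_cpp(NumericVector x) {
  NumericVector v(x.size()), ph(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double p = 0.5 * std::erfc(-x[i] * M_SQRT1_2);
    ph[i] = p;
    v[i] = x[i] * p;
  }
  v.attr("dim") = x.attr("dim");
  return List::create(_["v"] = v, _["p"] = ph);
}

// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector g, NumericVector x, NumericVector p) {
  const double inv_sqrt_2pi = 0.3989422804014327;
  NumericVector gx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) {
    gx[i] = g[i] * (p[i] + x[i] * inv_sqrt_2pi * std::exp(-0.5 * x[i] * x[i]));
  }
  gx.attr("dim") = g.attr("dim");
  return gx;
}
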