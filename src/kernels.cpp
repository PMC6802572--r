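// Core likelihood kernels.
//
// Buffer layouts (all column-major flat doubles):
//   internal partials : x[i + S*c + S*C*p]   (state fastest, then category, then pattern)
//   tip partials      : x[i + S*p]           (category-invariant)
//   compact tip       : int states[p], value >= S means "missing" (factor 1)
//   transition set    : P[i + S*j + S*S*c]   (P[i,j,c] = prob of i -> j in category c)
//
// Determinism contract: the serial, vectorized (S=4 unrolled) and threaded
// paths perform the identical sequence of floating-point operations per
// pattern, and patterns are mutually independent, so all paths produce
// bitwise-identical results for any worker count.

#include <Rcpp.h>
#include <thread>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct ChildView {
  int type;             // 0 compact tip, 1 tip partials, 2 internal partials
  const int *states;
  const double *vals;
};

ChildView make_child(int type, SEXP data) {
  ChildView ch;
  ch.type = type;
  ch.states = nullptr;
  ch.vals = nullptr;
  if (type == 0)
    ch.states = INTEGER(data);
  else
    ch.vals = REAL(data);
  return ch;
}

// sum_j P[i,j,c] * child[p,c,j]; compact tips use a column lookup instead.
inline double child_dot(const ChildView &ch, const double *Pc, int S, int C,
                        int c, int i, R_xlen_t p) {
  if (ch.type == 0) {
    int s = ch.states[p];
    if (s < 0 || s >= S) return 1.0;
    return Pc[i + (R_xlen_t)S * s];
  }
  const double *v = (ch.type == 1)
    ? ch.vals + (R_xlen_t)S * p
    : ch.vals + (R_xlen_t)S * ((R_xlen_t)c + (R_xlen_t)C * p);
  double acc = 0.0;
  for (int j = 0; j < S; ++j) acc += Pc[i + (R_xlen_t)S * j] * v[j];
  return acc;
}

// S = 4 specialisation; same left-to-right summation order as the generic
// loop (0 + x0 == x0 exactly for nonnegative x0), hence bitwise-equal.
inline double child_dot4(const ChildView &ch, const double *Pc, int C,
                         int c, int i, R_xlen_t p) {
  if (ch.type == 0) {
    int s = ch.states[p];
    if (s < 0 || s >= 4) return 1.0;
    return Pc[i + 4 * (R_xlen_t)s];
  }
  const double *v = (ch.type == 1)
    ? ch.vals + 4 * p
    : ch.vals + 4 * ((R_xlen_t)c + (R_xlen_t)C * p);
  return ((Pc[i] * v[0] + Pc[i + 4] * v[1]) + Pc[i + 8] * v[2]) + Pc[i + 12] * v[3];
}

void run_block(double *dest, const ChildView &c1, const double *P1,
               const ChildView &c2, const double *P2,
               int S, int C, R_xlen_t p0, R_xlen_t p1,
               bool rescale, double *scale) {
  const R_xlen_t SC = (R_xlen_t)S * C;
  for (R_xlen_t p = p0; p < p1; ++p) {
    double *d = dest + SC * p;
    for (int c = 0; c < C; ++c) {
      const double *P1c = P1 + (R_xlen_t)S * S * c;
      const double *P2c = P2 + (R_xlen_t)S * S * c;
      for (int i = 0; i < S; ++i) {
        double a = child_dot(c1, P1c, S, C, c, i, p);
        double b = child_dot(c2, P2c, S, C, c, i, p);
        d[(R_xlen_t)S * c + i] = a * b;
      }
    }
    if (rescale) {
      double m = 0.0;
      for (R_xlen_t k = 0; k < SC; ++k) if (d[k] > m) m = d[k];
      if (m > 0.0) {
        for (R_xlen_t k = 0; k < SC; ++k) d[k] /= m;
        scale[p] += std::log(m);
      }
    }
  }
}

void run_block4(double *dest, const ChildView &c1, const double *P1,
                const ChildView &c2, const double *P2,
                int C, R_xlen_t p0, R_xlen_t p1,
                bool rescale, double *scale) {
  const R_xlen_t SC = 4 * (R_xlen_t)C;
  for (R_xlen_t p = p0; p < p1; ++p) {
    double *d = dest + SC * p;
    for (int c = 0; c < C; ++c) {
      const double *P1c = P1 + 16 * (R_xlen_t)c;
      const double *P2c = P2 + 16 * (R_xlen_t)c;
      for (int i = 0; i < 4; ++i) {
        double a = child_dot4(c1, P1c, C, c, i, p);
        double b = child_dot4(c2, P2c, C, c, i, p);
        d[4 * (R_xlen_t)c + i] = a * b;
      }
    }
    if (rescale) {
      double m = 0.0;
      for (R_xlen_t k = 0; k < SC; ++k) if (d[k] > m) m = d[k];
      if (m > 0.0) {
        for (R_xlen_t k = 0; k < SC; ++k) d[k] /= m;
        scale[p] += std::log(m);
      }
    }
  }
}

void dispatch_block(double *dest, const ChildView &c1, const double *P1,
                    const ChildView &c2, const double *P2,
                    int S, int C, R_xlen_t p0, R_xlen_t p1,
                    bool rescale, double *scale, bool unrolled) {
  if (unrolled && S == 4)
    run_block4(dest, c1, P1, c2, P2, C, p0, p1, rescale, scale);
  else
    run_block(dest, c1, P1, c2, P2, S, C, p0, p1, rescale, scale);
}

} // namespace

// One partial-likelihood operation over the half-open pattern range
// [p0, p1).  Writes into `dest` in place; when `rescale` is true the
// per-pattern log scale factors are accumulated into `scale`.
// [[Rcpp::export]]
void update_partials_cpp(NumericVector dest,
                         int c1_type, SEXP c1_data, NumericVector P1,
                         int c2_type, SEXP c2_data, NumericVector P2,
                         int S, int C, int p0, int p1,
                         bool rescale, SEXP scale,
                         std::string impl, int workers) {
  ChildView c1 = make_child(c1_type, c1_data);
  ChildView c2 = make_child(c2_type, c2_data);
  double *d = REAL(dest);
  const double *P1p = REAL(P1);
  const double *P2p = REAL(P2);
  double *sc = rescale ? REAL(scale) : nullptr;
  const bool unrolled = (impl != "serial");

  if (impl == "threaded" && workers > 1 && p1 - p0 > 1) {
    R_xlen_t n = p1 - p0;
    int W = std::min<R_xlen_t>(workers, n);
    R_xlen_t chunk = (n + W - 1) / W;
    std::vector<std::thread> pool;
    pool.reserve(W);
    for (int w = 0; w < W; ++w) {
      R_xlen_t a = (R_xlen_t)p0 + chunk * w;
      R_xlen_t b = std::min<R_xlen_t>(p1, a + chunk);
      if (a >= b) break;
      pool.emplace_back([=]() {
        dispatch_block(d, c1, P1p, c2, P2p, S, C, a, b, rescale, sc, unrolled);
      });
    }
    for (auto &t : pool) t.join();
  } else {
    dispatch_block(d, c1, P1p, c2, P2p, S, C, p0, p1, rescale, sc, unrolled);
  }
}

// Per-pattern site log-likelihood at the root over [p0, p1):
//   L_p = sum_i pi_i sum_c w_c root[p,c,i];  out = log(L_p) + scale[p].
// Returns -Inf for L_p == 0 (caller reports underflow, no exception).
// [[Rcpp::export]]
NumericVector root_site_lnl_cpp(NumericVector root, int S, int C,
                                int p0, int p1,
                                NumericVector freqs,
                                NumericVector cat_weights,
                                SEXP scale) {
  const int n = p1 - p0;
  NumericVector out(n);
  const double *r = REAL(root);
  const double *pi = REAL(freqs);
  const double *w = REAL(cat_weights);
  const double *sc = Rf_isNull(scale) ? nullptr : REAL(scale);
  const R_xlen_t SC = (R_xlen_t)S * C;
  for (int p = p0; p < p1; ++p) {
    const double *d = r + SC * (R_xlen_t)p;
    double L = 0.0;
    for (int i = 0; i < S; ++i) {
      double acc = 0.0;
      for (int c = 0; c < C; ++c) acc += w[c] * d[(R_xlen_t)S * c + i];
      L += pi[i] * acc;
    }
    double v = std::log(L);
    if (sc) v += sc[p];
    out[p - p0] = v;
  }
  return out;
}

// Edge factorisation of the site likelihood, with optional derivative
// terms.  `parent` holds the partials of the tree minus the child subtree
// (internal layout); the child may be a tip or an internal buffer.
//   L_p  = sum_c w_c sum_i pi_i parent[p,c,i] * (sum_j  P[c,i,j] child[p,c,j])
//   L'_p, L''_p replace P by dP/dt, d2P/dt2.
// Returns site_lnl = log(L_p) + scale[p], and the ratios L'/L, L''/L
// (scale factors cancel in the ratios).
// [[Rcpp::export]]
List edge_site_terms_cpp(NumericVector parent,
                         int ch_type, SEXP ch_data,
                         NumericVector P, SEXP dP, SEXP d2P,
                         int S, int C, int p0, int p1,
                         NumericVector freqs, NumericVector cat_weights,
                         SEXP scale, bool want_derivs) {
  const int n = p1 - p0;
  NumericVector site_lnl(n), r1(n), r2(n);
  ChildView ch = make_child(ch_type, ch_data);
  const double *par = REAL(parent);
  const double *Pp = REAL(P);
  const double *d1p = want_derivs ? REAL(dP) : nullptr;
  const double *d2p = want_derivs ? REAL(d2P) : nullptr;
  const double *pi = REAL(freqs);
  const double *w = REAL(cat_weights);
  const double *sc = Rf_isNull(scale) ? nullptr : REAL(scale);
  const R_xlen_t SC = (R_xlen_t)S * C;

  for (int p = p0; p < p1; ++p) {
    const double *pv = par + SC * (R_xlen_t)p;
    double L = 0.0, L1 = 0.0, L2 = 0.0;
    for (int c = 0; c < C; ++c) {
      const double *Pc = Pp + (R_xlen_t)S * S * c;
      double inner = 0.0, inner1 = 0.0, inner2 = 0.0;
      for (int i = 0; i < S; ++i) {
        double f = pi[i] * pv[(R_xlen_t)S * c + i];
        inner += f * child_dot(ch, Pc, S, C, c, i, p);
        if (want_derivs) {
          const double *D1c = d1p + (R_xlen_t)S * S * c;
          const double *D2c = d2p + (R_xlen_t)S * S * c;
          inner1 += f * child_dot(ch, D1c, S, C, c, i, p);
          inner2 += f * child_dot(ch, D2c, S, C, c, i, p);
        }
      }
      L += w[c] * inner;
      L1 += w[c] * inner1;
      L2 += w[c] * inner2;
    }
    double v = std::log(L);
    if (sc) v += sc[p];
    site_lnl[p - p0] = v;
    if (want_derivs) {
      r1[p - p0] = L1 / L;
      r2[p - p0] = L2 / L;
    }
  }
  if (want_derivs)
    return List::create(_["site_lnl"] = site_lnl, _["r1"] = r1, _["r2"] = r2);
  return List::create(_["site_lnl"] = site_lnl);
}
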