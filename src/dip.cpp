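#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Hartigan-Hartigan dip statistic.
//
// D = min over unimodal CDFs U of sup_x |F_n(x) - U(x)|, where U is convex
// left of its mode and concave right of it, with a jump allowed only at the
// mode.  Computed by bisection on D with an exact feasibility check:
// does a unimodal CDF exist inside the band [F_n - D, F_n + D]?
//
// The band constrains U only at the distinct sample values ("gates"):
//   U(v_j)  >= lo_j = cum_j - D      (right limit of F_n)
//   U(v_j-) <= hi_j = prev_j + D     (left limit of F_n)
// On the convex flank the pointwise-minimal feasible function is the upper
// envelope of the anchor lines  lo_t + s_t (x - v_t)  where s_t is the
// smallest slope compatible with staying under every earlier upper gate;
// symmetrically the pointwise-maximal concave function is the lower envelope
// of  hi_t - sig_t (v_t - x).  Feasibility of a split (mode position)
// reduces to comparing these envelopes; the gap between them is convex in
// the mode position, so an interior mode is resolved by ternary search.

namespace {

struct Gates {
  std::vector<double> v, cum, prev;
};

Gates make_gates(const std::vector<double>& xs) {
  Gates g;
  const size_t n = xs.size();
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    g.v.push_back(xs[i]);
    g.prev.push_back(static_cast<double>(i) / n);
    g.cum.push_back(static_cast<double>(j) / n);
    i = j;
  }
  return g;
}

struct Bands {
  std::vector<double> lo, hi;
};

Bands make_bands(const Gates& g, double D) {
  const size_t m = g.v.size();
  Bands b;
  b.lo.resize(m);
  b.hi.resize(m);
  for (size_t j = 0; j < m; ++j) {
    b.lo[j] = std::max(0.0, g.cum[j] - D);
    b.hi[j] = std::min(1.0, g.prev[j] + D);
  }
  return b;
}

struct Sweeps {
  // convex (left) side
  std::vector<double> s, env, envx;
  int ok_upto;   // prefix 0..ok_upto satisfies env <= hi
  // concave (right) side
  std::vector<double> sig, benv, benvx;
  int ok_from;   // suffix ok_from..m-1 satisfies benv >= lo
};

const double EPS = 1e-12;

Sweeps run_sweeps(const std::vector<double>& v, const Bands& b) {
  const int m = static_cast<int>(v.size());
  Sweeps sw;
  sw.s.resize(m); sw.env.resize(m); sw.envx.resize(m);
  sw.sig.resize(m); sw.benv.resize(m); sw.benvx.resize(m);

  // left: minimal convex nondecreasing function through the band
  bool ok = true;
  sw.ok_upto = -1;
  for (int j = 0; j < m; ++j) {
    double sj = 0.0;
    for (int i = 0; i < j; ++i) {
      double sl = (b.lo[j] - b.hi[i]) / (v[j] - v[i]);
      if (sl > sj) sj = sl;
    }
    sw.s[j] = sj;
    double e = 0.0, ex = 0.0;  // the zero function is always an admissible floor
    for (int t = 0; t <= j; ++t) {
      double val = b.lo[t] + sw.s[t] * (v[j] - v[t]);
      if (val > e) e = val;
      if (t < j && val > ex) ex = val;
    }
    sw.env[j] = e;
    sw.envx[j] = ex;
    if (ok && e <= b.hi[j] + EPS) sw.ok_upto = j; else ok = false;
  }

  // right: maximal concave nondecreasing function through the band
  ok = true;
  sw.ok_from = m;
  for (int j = m - 1; j >= 0; --j) {
    double sg = 0.0;
    for (int i = j + 1; i < m; ++i) {
      double sl = (b.lo[i] - b.hi[j]) / (v[i] - v[j]);
      if (sl > sg) sg = sl;
    }
    sw.sig[j] = sg;
    double e = 1.0, ex = 1.0;  // the unit function is always an admissible cap
    for (int t = j; t < m; ++t) {
      double val = b.hi[t] - sw.sig[t] * (v[t] - v[j]);
      if (val < e) e = val;
      if (t > j && val < ex) ex = val;
    }
    sw.benv[j] = e;
    sw.benvx[j] = ex;
    if (ok && e >= b.lo[j] - EPS) sw.ok_from = j; else ok = false;
  }
  return sw;
}

// value of the convex envelope at x plus the range of slopes among the
// lines attaining it (sub-derivative interval)
struct EnvPt { double val, slo, shi; };

EnvPt eval_A(double x, int k, const std::vector<double>& v,
             const Bands& b, const Sweeps& sw) {
  double e = 0.0, slo = 0.0, shi = 0.0;
  for (int t = 0; t <= k; ++t) {
    double val = b.lo[t] + sw.s[t] * (x - v[t]);
    if (val > e + 1e-13) { e = val; slo = shi = sw.s[t]; }
    else if (val > e - 1e-13) {
      if (sw.s[t] < slo) slo = sw.s[t];
      if (sw.s[t] > shi) shi = sw.s[t];
    }
  }
  return {e, slo, shi};
}

EnvPt eval_B(double x, int k, const std::vector<double>& v,
             const Bands& b, const Sweeps& sw) {
  const int m = static_cast<int>(v.size());
  double e = 1.0, slo = 0.0, shi = 0.0;
  for (int t = k; t < m; ++t) {
    double val = b.hi[t] - sw.sig[t] * (v[t] - x);
    if (val < e - 1e-13) { e = val; slo = shi = sw.sig[t]; }
    else if (val < e + 1e-13) {
      if (sw.sig[t] < slo) slo = sw.sig[t];
      if (sw.sig[t] > shi) shi = sw.sig[t];
    }
  }
  return {e, slo, shi};
}

bool feasible(const Gates& g, double D) {
  const int m = static_cast<int>(g.v.size());
  if (m == 1) return true;  // a point mass is unimodal
  const Bands b = make_bands(g, D);
  const Sweeps sw = run_sweeps(g.v, b);

  if (sw.ok_upto == m - 1) return true;  // mode right of all data
  if (sw.ok_from == 0) return true;      // mode left of all data

  // atom of U exactly at gate j: upper gate binds the left limit (convex
  // side), lower gate binds the value (concave side)
  for (int j = 0; j < m; ++j) {
    if (j > 0 && sw.ok_upto < j - 1) continue;
    if (j < m - 1 && sw.ok_from > j + 1) continue;
    double Aj = (j == 0) ? 0.0 : sw.envx[j];
    double Bj = (j == m - 1) ? 1.0 : sw.benvx[j];
    if (Aj <= b.hi[j] + EPS && Bj >= b.lo[j] - EPS && Aj <= Bj + EPS)
      return true;
  }

  // mode strictly inside the interval (v_k, v_{k+1})
  for (int k = 0; k + 1 < m; ++k) {
    if (sw.ok_upto < k || sw.ok_from > k + 1) continue;
    if (sw.env[k] > sw.benv[k + 1] + EPS) continue;  // necessary condition
    EnvPt aL = eval_A(g.v[k], k, g.v, b, sw);
    EnvPt bL = eval_B(g.v[k], k + 1, g.v, b, sw);
    if (aL.val - bL.val <= EPS) return true;
    // phi = A - B is convex; if its right-derivative at the left end is
    // non-negative the minimum sits there and the split is infeasible
    if (aL.shi - bL.slo >= 0.0) continue;
    EnvPt aR = eval_A(g.v[k + 1], k, g.v, b, sw);
    EnvPt bR = eval_B(g.v[k + 1], k + 1, g.v, b, sw);
    if (aR.val - bR.val <= EPS) return true;
    if (aR.slo - bR.shi <= 0.0) continue;  // min at right end, positive
    // interior minimum: ternary search
    double a = g.v[k], c = g.v[k + 1];
    for (int it = 0; it < 100; ++it) {
      double m1 = a + (c - a) / 3.0, m2 = c - (c - a) / 3.0;
      double p1 = eval_A(m1, k, g.v, b, sw).val - eval_B(m1, k + 1, g.v, b, sw).val;
      double p2 = eval_A(m2, k, g.v, b, sw).val - eval_B(m2, k + 1, g.v, b, sw).val;
      if (std::min(p1, p2) <= EPS) return true;
      if (p1 < p2) c = m2; else a = m1;
      if (c - a < 1e-12 * (g.v[m - 1] - g.v[0])) break;
    }
  }
  return false;
}

double dip_of_sorted(const std::vector<double>& xs) {
  const Gates g = make_gates(xs);
  if (g.v.size() == 1) return 0.0;
  double lo = 0.0, hi = 0.5;
  for (int it = 0; it < 64; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(g, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

} // namespace

// [[Rcpp::export]]
double cpp_dip(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_of_sorted(xs);
}

// [[Rcpp::export]]
NumericVector cpp_dip_rows(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nr);
  std::vector<double> xs(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) xs[j] = m(i, j);
    std::sort(xs.begin(), xs.end());
    out[i] = dip_of_sorted(xs);
  }
  return out;
}
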