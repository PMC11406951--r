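// Dense bounded-variable two-phase primal simplex kernel.
//
// Solves max c'x s.t. A x = b, l <= x <= u with finite bounds. Explicit
// basis inverse with eta updates; Dantzig pricing switching to Bland's rule
// after a run of degenerate steps (anti-cycling); artificial variables with
// bounds [0, big] in phase 1, clamped to [0, 0] in phase 2.
//
// Status codes returned: 0 optimal, 1 infeasible, 2 unbounded,
// 3 iteration limit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

enum VStat { BASIC = 0, AT_LOWER = 1, AT_UPPER = 2 };

struct State {
  int m, n, nt;
  std::vector<double> Afull;  // column-major m x nt
  std::vector<double> lo, up;
  std::vector<int> st;
  std::vector<int> basis;     // length m
  std::vector<double> xB;
  std::vector<double> Binv;   // column-major m x m
  double tol;

  double a(int i, int j) const { return Afull[i + (size_t)m * j]; }
  double binv(int i, int k) const { return Binv[i + (size_t)m * k]; }
};

// returns 0 optimal, 2 unbounded, 3 iteration limit
int run_simplex(State &s, const std::vector<double> &cvec, int phase) {
  const int m = s.m, nt = s.nt;
  const double tol = s.tol;
  const long max_iter = 500L * (nt + 10);
  int degen = 0;
  bool bland = false;
  std::vector<double> y(m), d(nt), delta(m), g(m);

  for (long it = 0; it < max_iter; ++it) {
    // y = Binv' cB ; d = c - y' Afull
    for (int k = 0; k < m; ++k) {
      double acc = 0.0;
      for (int i = 0; i < m; ++i) acc += cvec[s.basis[i]] * s.binv(i, k);
      y[k] = acc;
    }
    for (int j = 0; j < nt; ++j) {
      double acc = cvec[j];
      const double *col = &s.Afull[(size_t)m * j];
      for (int k = 0; k < m; ++k) acc -= y[k] * col[k];
      d[j] = acc;
    }
    // entering variable
    int enter = -1;
    double best = 0.0;
    for (int j = 0; j < nt; ++j) {
      if (s.st[j] == BASIC || s.lo[j] >= s.up[j]) continue;
      bool ok = (s.st[j] == AT_LOWER && d[j] > tol) ||
                (s.st[j] == AT_UPPER && d[j] < -tol);
      if (!ok) continue;
      if (bland) { enter = j; break; }
      double mag = std::fabs(d[j]);
      if (mag > best) { best = mag; enter = j; }
    }
    if (enter < 0) return 0;  // optimal

    const double sgn = (s.st[enter] == AT_LOWER) ? 1.0 : -1.0;
    const double *col = &s.Afull[(size_t)m * enter];
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int k = 0; k < m; ++k) acc += s.binv(i, k) * col[k];
      delta[i] = acc;
      g[i] = sgn * acc;
    }
    // ratio test
    double t_bound = s.up[enter] - s.lo[enter];
    double t_star = t_bound;
    double min_lim = R_PosInf;
    for (int i = 0; i < m; ++i) {
      double lim = R_PosInf;
      if (g[i] > tol) lim = (s.xB[i] - s.lo[s.basis[i]]) / g[i];
      else if (g[i] < -tol) lim = (s.up[s.basis[i]] - s.xB[i]) / (-g[i]);
      if (lim < 0) lim = 0;
      if (lim < min_lim) min_lim = lim;
    }
    if (min_lim < t_star) t_star = min_lim;
    if (!R_FINITE(t_star)) {
      if (phase == 2) return 2;  // unbounded
      t_star = t_bound;          // cannot happen with finite bounds
    }
    if (t_star < tol) { if (++degen > nt + 50) bland = true; }
    else degen = 0;

    const double tie = tol * (1.0 + std::fabs(t_star));
    if (t_bound <= min_lim + tie) {
      // bound flip, basis unchanged
      s.st[enter] = (s.st[enter] == AT_LOWER) ? AT_UPPER : AT_LOWER;
      for (int i = 0; i < m; ++i) s.xB[i] -= g[i] * t_bound;
    } else {
      // leaving row: among ratio ties pick max |g| (or min basis idx, Bland)
      int rr = -1;
      double best_g = -1.0;
      int best_idx = INT_MAX;
      for (int i = 0; i < m; ++i) {
        double lim = R_PosInf;
        if (g[i] > tol) lim = (s.xB[i] - s.lo[s.basis[i]]) / g[i];
        else if (g[i] < -tol) lim = (s.up[s.basis[i]] - s.xB[i]) / (-g[i]);
        if (lim < 0) lim = 0;
        if (lim <= t_star + tie) {
          if (bland) {
            if (s.basis[i] < best_idx) { best_idx = s.basis[i]; rr = i; }
          } else if (std::fabs(g[i]) > best_g) {
            best_g = std::fabs(g[i]); rr = i;
          }
        }
      }
      if (rr < 0) return 3;  // numerical breakdown
      int leave = s.basis[rr];
      s.st[leave] = (g[rr] > 0) ? AT_LOWER : AT_UPPER;
      for (int i = 0; i < m; ++i) s.xB[i] -= g[i] * t_star;
      s.xB[rr] = (sgn > 0) ? s.lo[enter] + t_star : s.up[enter] - t_star;
      s.basis[rr] = enter;
      s.st[enter] = BASIC;
      double piv = delta[rr];
      for (int k = 0; k < m; ++k) s.Binv[rr + (size_t)m * k] /= piv;
      for (int i = 0; i < m; ++i) {
        if (i == rr) continue;
        double f = delta[i];
        if (f == 0.0) continue;
        for (int k = 0; k < m; ++k)
          s.Binv[i + (size_t)m * k] -= f * s.Binv[rr + (size_t)m * k];
      }
    }
    // clamp roundoff
    for (int i = 0; i < m; ++i) {
      double l = s.lo[s.basis[i]] - 1e-7, u = s.up[s.basis[i]] + 1e-7;
      if (s.xB[i] < l) s.xB[i] = l;
      if (s.xB[i] > u) s.xB[i] = u;
    }
  }
  return 3;
}

}  // namespace

namespace {

// Build a state with artificial basis from scratch and run phase 1.
// Returns 0 on success (feasible), 1 infeasible, 3 breakdown.
int setup_phase1(State &s, NumericMatrix A, NumericVector lower,
                 NumericVector upper, NumericVector b, double tol) {
  const int m = A.nrow(), n = A.ncol();
  const int nt = n + m;
  s.m = m; s.n = n; s.nt = nt; s.tol = tol;
  s.Afull.assign((size_t)m * nt, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) s.Afull[i + (size_t)m * j] = A(i, j);

  std::vector<double> x0(n);
  s.st.assign(nt, AT_LOWER);
  for (int j = 0; j < n; ++j) {
    if (std::fabs(lower[j]) <= std::fabs(upper[j])) {
      x0[j] = lower[j]; s.st[j] = AT_LOWER;
    } else {
      x0[j] = upper[j]; s.st[j] = AT_UPPER;
    }
  }
  std::vector<double> r(m);
  double big = 1.0;
  for (int i = 0; i < m; ++i) {
    double acc = b[i];
    for (int j = 0; j < n; ++j) acc -= A(i, j) * x0[j];
    r[i] = acc;
    big += std::fabs(acc);
  }
  for (int i = 0; i < m; ++i) {
    double sg = (r[i] >= 0) ? 1.0 : -1.0;
    s.Afull[i + (size_t)m * (n + i)] = sg;
  }
  s.lo.assign(nt, 0.0);
  s.up.assign(nt, 0.0);
  for (int j = 0; j < n; ++j) { s.lo[j] = lower[j]; s.up[j] = upper[j]; }
  for (int i = 0; i < m; ++i) { s.lo[n + i] = 0.0; s.up[n + i] = big; }
  s.basis.resize(m);
  s.xB.resize(m);
  s.Binv.assign((size_t)m * m, 0.0);
  for (int i = 0; i < m; ++i) {
    s.basis[i] = n + i;
    s.st[n + i] = BASIC;
    s.xB[i] = std::fabs(r[i]);
    s.Binv[i + (size_t)m * i] = (r[i] >= 0) ? 1.0 : -1.0;
  }
  std::vector<double> c1(nt, 0.0);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
  int st1 = run_simplex(s, c1, 1);
  if (st1 != 0) return st1;
  double art_sum = 0.0;
  for (int i = 0; i < m; ++i) if (s.basis[i] >= n) art_sum += s.xB[i];
  double bmax = 0.0;
  for (int i = 0; i < m; ++i) bmax = std::max(bmax, std::fabs(b[i]));
  if (art_sum > 1e-7 * (1.0 + bmax)) return 1;
  for (int i = 0; i < m; ++i) { s.lo[n + i] = 0.0; s.up[n + i] = 0.0; }
  return 0;
}

void extract_x(const State &s, std::vector<double> &x) {
  const int n = s.n;
  x.assign(n, 0.0);
  for (int j = 0; j < n; ++j)
    x[j] = (s.st[j] == AT_LOWER) ? s.lo[j]
           : (s.st[j] == AT_UPPER ? s.up[j] : 0.0);
  for (int i = 0; i < s.m; ++i)
    if (s.basis[i] < n) x[s.basis[i]] = s.xB[i];
}

}  // namespace

// Warm-started flux variability: solve min/max of each of the first
// n_front variables over {A x = b, l <= x <= u}, reusing the basis between
// solves. If values is false, variables already seen carrying more than
// tol_blocked flux in any solution are skipped (their min/max return NA);
// the blocked flag is exact either way.
// [[Rcpp::export]]
List fva_bounded_cpp(NumericMatrix A, NumericVector lower,
                     NumericVector upper, NumericVector b, int n_front,
                     bool values, double tol, double tol_blocked) {
  State s;
  int st1 = setup_phase1(s, A, lower, upper, b, tol);
  if (st1 != 0) return List::create(_["status"] = st1);
  const int n = s.n;
  std::vector<double> x;
  NumericVector vmin(n_front, NA_REAL), vmax(n_front, NA_REAL);
  LogicalVector blocked(n_front, true);
  std::vector<bool> carries(n_front, false);
  std::vector<double> c(s.nt, 0.0);

  auto mark = [&](const std::vector<double> &xx) {
    for (int j = 0; j < n_front; ++j)
      if (std::fabs(xx[j]) > tol_blocked) carries[j] = true;
  };

  for (int j = 0; j < n_front; ++j) {
    if (!values && carries[j]) { blocked[j] = false; continue; }
    // maximize v_j
    std::fill(c.begin(), c.end(), 0.0);
    c[j] = 1.0;
    if (run_simplex(s, c, 2) != 0) return List::create(_["status"] = 3);
    extract_x(s, x);
    mark(x);
    vmax[j] = x[j];
    if (!values && carries[j]) { blocked[j] = false; continue; }
    // minimize v_j
    c[j] = -1.0;
    if (run_simplex(s, c, 2) != 0) return List::create(_["status"] = 3);
    extract_x(s, x);
    mark(x);
    vmin[j] = x[j];
    blocked[j] = std::fabs(vmin[j]) <= tol_blocked &&
                 std::fabs(vmax[j]) <= tol_blocked;
  }
  if (!values) {
    for (int j = 0; j < n_front; ++j) blocked[j] = !carries[j];
  }
  return List::create(_["status"] = 0, _["min"] = vmin, _["max"] = vmax,
                      _["blocked"] = blocked);
}

// [[Rcpp::export]]
List simplex_bounded_cpp(NumericMatrix A, NumericVector obj,
                         NumericVector lower, NumericVector upper,
                         NumericVector b, bool maximize, double tol) {
  const int m = A.nrow(), n = A.ncol();
  const int nt = n + m;
  State s;
  s.m = m; s.n = n; s.nt = nt; s.tol = tol;
  s.Afull.assign((size_t)m * nt, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) s.Afull[i + (size_t)m * j] = A(i, j);

  std::vector<double> cstruct(n);
  for (int j = 0; j < n; ++j) cstruct[j] = maximize ? obj[j] : -obj[j];

  // initial nonbasic point: structural vars at the bound nearer zero
  std::vector<double> x0(n);
  s.st.assign(nt, AT_LOWER);
  for (int j = 0; j < n; ++j) {
    if (std::fabs(lower[j]) <= std::fabs(upper[j])) {
      x0[j] = lower[j]; s.st[j] = AT_LOWER;
    } else {
      x0[j] = upper[j]; s.st[j] = AT_UPPER;
    }
  }
  std::vector<double> r(m);
  double big = 1.0;
  for (int i = 0; i < m; ++i) {
    double acc = b[i];
    for (int j = 0; j < n; ++j) acc -= A(i, j) * x0[j];
    r[i] = acc;
    big += std::fabs(acc);
  }
  for (int i = 0; i < m; ++i) {
    double sg = (r[i] >= 0) ? 1.0 : -1.0;
    s.Afull[i + (size_t)m * (n + i)] = sg;
  }
  s.lo.assign(nt, 0.0);
  s.up.assign(nt, 0.0);
  for (int j = 0; j < n; ++j) { s.lo[j] = lower[j]; s.up[j] = upper[j]; }
  for (int i = 0; i < m; ++i) { s.lo[n + i] = 0.0; s.up[n + i] = big; }
  s.basis.resize(m);
  s.xB.resize(m);
  s.Binv.assign((size_t)m * m, 0.0);
  for (int i = 0; i < m; ++i) {
    s.basis[i] = n + i;
    s.st[n + i] = BASIC;
    s.xB[i] = std::fabs(r[i]);
    s.Binv[i + (size_t)m * i] = (r[i] >= 0) ? 1.0 : -1.0;
  }

  // phase 1
  std::vector<double> c1(nt, 0.0);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
  int st1 = run_simplex(s, c1, 1);
  if (st1 != 0) return List::create(_["status"] = st1);
  double art_sum = 0.0;
  for (int i = 0; i < m; ++i) if (s.basis[i] >= n) art_sum += s.xB[i];
  double bmax = 0.0;
  for (int i = 0; i < m; ++i) bmax = std::max(bmax, std::fabs(b[i]));
  if (art_sum > 1e-7 * (1.0 + bmax)) return List::create(_["status"] = 1);

  // phase 2: clamp artificials
  for (int i = 0; i < m; ++i) { s.lo[n + i] = 0.0; s.up[n + i] = 0.0; }
  std::vector<double> c2(nt, 0.0);
  for (int j = 0; j < n; ++j) c2[j] = cstruct[j];
  int st2 = run_simplex(s, c2, 2);
  if (st2 != 0) return List::create(_["status"] = st2);

  NumericVector x(n);
  for (int j = 0; j < n; ++j) {
    x[j] = (s.st[j] == AT_LOWER) ? s.lo[j] : (s.st[j] == AT_UPPER ? s.up[j] : 0.0);
  }
  for (int i = 0; i < m; ++i) {
    if (s.basis[i] < n) x[s.basis[i]] = s.xB[i];
  }
  double val = 0.0;
  for (int j = 0; j < n; ++j) {
    if (x[j] < lower[j]) x[j] = lower[j];
    if (x[j] > upper[j]) x[j] = upper[j];
    val += obj[j] * x[j];
  }
  return List::create(_["status"] = 0, _["objective"] = val, _["x"] = x);
}
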