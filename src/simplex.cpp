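// Dense bounded-variable primal simplex for the small LPs arising in
// flux balance analysis (tens of reactions, a handful of balanced
// metabolites).  Two phases: artificial variables give the initial basis,
// phase 2 optimizes the user objective.  Nonbasic variables sit at a
// finite bound (or at 0 when free); their status is tracked explicitly and
// the ratio test allows bound-to-bound flips.  Dantzig pricing with a
// Bland's-rule fallback guards against cycling on degenerate polytopes.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

enum VStat { BASIC = 0, AT_LO = 1, AT_HI = 2, FREE = 3 };

// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit

struct LPResult {
  int status;
  std::vector<double> x;
  double objective;
  int iterations;
};

static LPResult solve_core(const double* A, int m, int n, const double* b,
                           const double* cobj, const double* lb,
                           const double* ub, bool maximize, double tol,
                           int max_iter) {
  const int N = n + m;          // structural + artificial
  if (max_iter <= 0) max_iter = 500 + 60 * (m + n);
  auto Aat = [&](int i, int j) -> double { return A[i + static_cast<size_t>(j) * m]; };

  std::vector<double> c(N, 0.0);
  for (int j = 0; j < n; ++j) c[j] = maximize ? cobj[j] : -cobj[j];

  std::vector<double> lo(N), hi(N);
  for (int j = 0; j < n; ++j) { lo[j] = lb[j]; hi[j] = ub[j]; }
  for (int j = n; j < N; ++j) { lo[j] = 0.0; hi[j] = INF; }

  // nonbasic starting point and explicit status
  std::vector<int> stat(N);
  auto nb_value = [&](int j) -> double {
    switch (stat[j]) {
      case AT_LO: return lo[j];
      case AT_HI: return hi[j];
      default: return 0.0;      // FREE
    }
  };
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(lo[j])) stat[j] = AT_LO;
    else if (std::isfinite(hi[j])) stat[j] = AT_HI;
    else stat[j] = FREE;
  }

  std::vector<double> resid(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += Aat(i, j) * nb_value(j);
    resid[i] = b[i] - s;
  }

  // full tableau T = B^{-1} [A | A_art]; basis starts as the artificials
  std::vector<double> T(static_cast<size_t>(m) * N, 0.0);
  auto Tat = [&](int i, int j) -> double& { return T[static_cast<size_t>(i) * N + j]; };
  for (int i = 0; i < m; ++i) {
    double sgn = (resid[i] >= 0.0) ? 1.0 : -1.0;
    for (int j = 0; j < n; ++j) Tat(i, j) = sgn * Aat(i, j);
    Tat(i, n + i) = 1.0;        // after scaling the row by sgn
    stat[n + i] = BASIC;
  }
  std::vector<double> bw(m);    // values of the basic variables
  for (int i = 0; i < m; ++i) bw[i] = std::fabs(resid[i]);

  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) basis[i] = n + i;

  // phase-1 objective: maximize -sum(artificials)
  std::vector<double> cw(N, 0.0);
  for (int j = n; j < N; ++j) cw[j] = -1.0;

  int phase = 1;
  int iter = 0;
  bool bland = false;
  int status = 0;

  while (true) {
    if (++iter > max_iter) { status = 3; break; }
    if (iter > max_iter / 2) bland = true;   // anti-cycling fallback

    // reduced costs d = c - c_B^T T
    std::vector<double> d(N);
    for (int j = 0; j < N; ++j) d[j] = cw[j];
    for (int i = 0; i < m; ++i) {
      double cb = cw[basis[i]];
      if (cb != 0.0) for (int j = 0; j < N; ++j) d[j] -= cb * Tat(i, j);
    }

    // pricing
    int jin = -1; double best = tol; int dir = 0;
    for (int j = 0; j < N; ++j) {
      if (stat[j] == BASIC) continue;
      if (lo[j] == hi[j]) continue;               // fixed, cannot move
      double gain = 0.0; int dd = 0;
      if ((stat[j] == AT_LO || stat[j] == FREE) && d[j] > tol) {
        gain = d[j]; dd = +1;
      } else if ((stat[j] == AT_HI || stat[j] == FREE) && -d[j] > tol) {
        gain = -d[j]; dd = -1;
      }
      if (dd != 0) {
        if (bland) { jin = j; dir = dd; break; }
        if (gain > best) { best = gain; jin = j; dir = dd; }
      }
    }
    if (jin < 0) {
      if (phase == 1) {
        double art = 0.0;
        for (int i = 0; i < m; ++i) if (basis[i] >= n) art += bw[i];
        if (art > 1e-7) { status = 1; break; }
        for (int j = n; j < N; ++j) { lo[j] = 0.0; hi[j] = 0.0; }
        for (int j = 0; j < N; ++j) cw[j] = c[j];
        phase = 2; bland = false; iter = 0;
        continue;
      }
      status = 0; break;
    }

    // ratio test: smallest step, ties to the lowest basic variable index
    double tmax = INF; int rleave = -1; int leave_to = 0;
    double span = hi[jin] - lo[jin];
    if (std::isfinite(span)) tmax = span;       // bound-to-bound flip
    for (int i = 0; i < m; ++i) {
      double a = Tat(i, jin) * dir;
      int jb = basis[i];
      double t; int to;
      if (a > tol && std::isfinite(lo[jb])) {
        t = (bw[i] - lo[jb]) / a; to = -1;
      } else if (a < -tol && std::isfinite(hi[jb])) {
        t = (hi[jb] - bw[i]) / (-a); to = +1;
      } else continue;
      if (t < 0.0) t = 0.0;
      bool take = (t < tmax - 1e-12) ||
                  (t <= tmax + 1e-12 && rleave >= 0 && jb < basis[rleave]);
      if (rleave < 0 && t <= tmax) take = true;
      if (take) { tmax = t; rleave = i; leave_to = to; }
    }
    if (!std::isfinite(tmax)) { status = (phase == 1) ? 1 : 2; break; }

    double xin_old = nb_value(jin);
    for (int i = 0; i < m; ++i) bw[i] -= dir * tmax * Tat(i, jin);

    if (rleave < 0) {
      // bound flip: entering variable moves to its opposite bound
      stat[jin] = (dir > 0) ? AT_HI : AT_LO;
      continue;
    }

    int jout = basis[rleave];
    stat[jout] = (leave_to < 0) ? AT_LO : AT_HI;

    double piv = Tat(rleave, jin);
    if (std::fabs(piv) < 1e-11) { status = 3; break; }
    double inv = 1.0 / piv;
    for (int j = 0; j < N; ++j) Tat(rleave, j) *= inv;
    for (int i = 0; i < m; ++i) {
      if (i == rleave) continue;
      double f = Tat(i, jin);
      if (f != 0.0) for (int j = 0; j < N; ++j) Tat(i, j) -= f * Tat(rleave, j);
    }
    basis[rleave] = jin;
    stat[jin] = BASIC;
    bw[rleave] = xin_old + dir * tmax;
  }

  // assemble structural solution
  std::vector<double> x(N);
  for (int j = 0; j < N; ++j) x[j] = (stat[j] == BASIC) ? 0.0 : nb_value(j);
  for (int i = 0; i < m; ++i) x[basis[i]] = bw[i];
  LPResult out;
  out.status = status;
  out.x.assign(x.begin(), x.begin() + n);
  out.objective = 0.0;
  for (int j = 0; j < n; ++j) out.objective += cobj[j] * out.x[j];
  out.iterations = iter;
  return out;
}

// [[Rcpp::export(name = ".simplex_cpp")]]
List simplex_cpp(NumericMatrix A, NumericVector b, NumericVector cobj,
                 NumericVector lb, NumericVector ub,
                 bool maximize = true, double tol = 1e-9,
                 int max_iter = 0) {
  LPResult r = solve_core(A.begin(), A.nrow(), A.ncol(), b.begin(),
                          cobj.begin(), lb.begin(), ub.begin(),
                          maximize, tol, max_iter);
  return List::create(_["status"] = r.status,
                      _["x"] = NumericVector(r.x.begin(), r.x.end()),
                      _["objective"] = r.objective,
                      _["iterations"] = r.iterations);
}

// Lexicographic driver: solves the priority levels on one augmented LP,
// pinning each optimum via the bounds of its fix slack before moving on.
// Level 1 is the phase-I penalty (minimized; its fix slack floor is 0).
// [[Rcpp::export(name = ".lex_cpp")]]
List lex_cpp(NumericMatrix A, NumericVector b, NumericMatrix C,
             LogicalVector maximize, NumericVector LO, NumericVector HI,
             IntegerVector fix_col, double fix_abs = 1e-9,
             double fix_rel = 1e-7, double tol = 1e-9) {
  const int m = A.nrow();
  const int n = A.ncol();
  const int K = C.nrow();
  std::vector<double> lo(LO.begin(), LO.end());
  std::vector<double> hi(HI.begin(), HI.end());
  std::vector<double> ck(n);
  NumericVector objs(K);
  LPResult r;
  int level = K;
  int status = 0;
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < n; ++j) ck[j] = C(k, j);
    r = solve_core(A.begin(), m, n, b.begin(), ck.data(), lo.data(),
                   hi.data(), maximize[k], tol, 0);
    if (r.status != 0) { status = r.status; level = k + 1; break; }
    objs[k] = r.objective;
    if (k < K - 1) {
      double z = r.objective;
      double delta = std::max(fix_abs, fix_rel * std::fabs(z));
      int fc = fix_col[k] - 1;            // 1-based from R
      lo[fc] = (k == 0) ? std::max(0.0, z - delta) : z - delta;
      hi[fc] = z + delta;
    }
  }
  return List::create(_["status"] = status,
                      _["x"] = NumericVector(r.x.begin(), r.x.end()),
                      _["objectives"] = objs,
                      _["level"] = level);
}
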