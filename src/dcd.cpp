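#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Dual coordinate descent for the linear SVM dual
//   min_a  (1/2) a' Qbar a - e'a,   0 <= a_i <= U
// where Qbar_ij = y_i y_j x_i'x_j (+ D on the diagonal for L2 hinge),
// maintaining w = sum_i a_i y_i x_i incrementally after every update.
//
// The design matrix is passed transposed in CSC form (xp, xi, xv), so the
// nonzeros of instance i occupy xp[i]..xp[i+1]-1.
//
// Stopping rule: max |projected gradient| over an epoch <= tol.
// Coordinate order: a fresh seeded Fisher-Yates permutation each epoch.

namespace {

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double dot_w(const double* w, const int* xi, const double* xv,
                    int lo, int hi) {
  double s = 0.0;
  for (int k = lo; k < hi; ++k) s += w[xi[k]] * xv[k];
  return s;
}

} // namespace

// [[Rcpp::export(name = ".dcd_solve_cpp")]]
List dcd_solve_cpp(IntegerVector xp, IntegerVector xi, NumericVector xv,
                   int n, int l, NumericVector yb, double C,
                   double tol, int max_epochs, int seed,
                   bool l2_hinge, bool shrinking, bool trace) {
  const double D = l2_hinge ? 1.0 / (2.0 * C) : 0.0;
  const double U = l2_hinge ? R_PosInf : C;

  std::vector<double> alpha(n, 0.0), w(l, 0.0), Qii(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  // cache Q_ii; instances with empty rows have constant gradient -1:
  // their optimum is alpha_i = U (L1: C; L2: 1/D = 2C), contributing
  // nothing to w -- fix analytically and keep them out of the sweep.
  int active = 0;
  for (int i = 0; i < n; ++i) {
    double q = D;
    for (int k = xp[i]; k < xp[i + 1]; ++k) q += xv[k] * xv[k];
    Qii[i] = q;
    if (xp[i + 1] == xp[i]) {
      alpha[i] = l2_hinge ? 2.0 * C : C;
    } else {
      idx[active++] = i;
    }
  }

  XorShift64 rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> tr_viol, tr_dual;
  std::vector<int> tr_epoch;

  int n_active = active;          // shrinking working-set size
  double M_prev = R_PosInf;       // last epoch's max |PG| (shrink threshold)
  bool converged = false;
  double last_viol = R_PosInf;
  int epoch = 0;

  while (epoch < max_epochs) {
    ++epoch;
    // Fisher-Yates over the active slice
    for (int k = n_active - 1; k > 0; --k) {
      int j = rng.below(k + 1);
      std::swap(idx[k], idx[j]);
    }
    double max_pg = 0.0;
    for (int k = 0; k < n_active; ++k) {
      int i = idx[k];
      double yi = yb[i];
      double G = yi * dot_w(w.data(), &xi[0], &xv[0], xp[i], xp[i + 1])
                 - 1.0 + D * alpha[i];
      double PG = G;
      bool shrink_i = false;
      if (alpha[i] <= 0.0) {
        if (G > 0.0) PG = 0.0;
        if (shrinking && G > M_prev) shrink_i = true;
      } else if (alpha[i] >= U) {
        if (G < 0.0) PG = 0.0;
        if (shrinking && G < -M_prev) shrink_i = true;
      }
      if (shrink_i) {
        std::swap(idx[k], idx[--n_active]);
        --k;
        continue;
      }
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_old = alpha[i];
        double a_new = a_old - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > U) a_new = U;
        alpha[i] = a_new;
        double d = (a_new - a_old) * yi;
        for (int t = xp[i]; t < xp[i + 1]; ++t) w[xi[t]] += d * xv[t];
      }
    }
    last_viol = max_pg;
    if (trace) {
      double dual = 0.0, wsq = 0.0, asq = 0.0;
      for (int j = 0; j < l; ++j) wsq += w[j] * w[j];
      for (int i = 0; i < n; ++i) { dual += alpha[i]; asq += alpha[i] * alpha[i]; }
      dual -= 0.5 * wsq + 0.5 * D * asq;
      tr_epoch.push_back(epoch); tr_viol.push_back(max_pg); tr_dual.push_back(dual);
    }
    if (max_pg <= tol) {
      if (shrinking && n_active < active) {
        // working set converged: restore all coordinates and re-verify
        n_active = active;
        M_prev = R_PosInf;
        continue;
      }
      converged = true;
      break;
    }
    M_prev = shrinking ? (max_pg > 0 ? max_pg : R_PosInf) : R_PosInf;
  }

  List out = List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["epochs"] = epoch,
    _["converged"] = converged,
    _["violation"] = last_viol);
  if (trace) {
    out["trace"] = DataFrame::create(
      _["epoch"] = IntegerVector(tr_epoch.begin(), tr_epoch.end()),
      _["violation"] = NumericVector(tr_viol.begin(), tr_viol.end()),
      _["dual_objective"] = NumericVector(tr_dual.begin(), tr_dual.end()));
  }
  return out;
}
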