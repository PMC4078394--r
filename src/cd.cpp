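// Cyclic coordinate descent for the lasso objective
//   f(x) = (1/(2n)) ||y - A x||_2^2 + lambda ||x||_1
// on a column-standardized design (||A_j||^2 = n under the 1/n variance
// convention), so the coordinate update is a single soft-threshold:
//   x_j <- S(x_j + A_j'r / n, lambda),  r the current residual.
//
// Two modes share the same update rule and the same convergence criterion
// (fractional objective change over one sweep < tol):
//  * plain: full cyclic sweeps over all p coordinates;
//  * active-set: cyclic sweeps restricted to an ever-active set, with a
//    BLAS-level full-gradient KKT screen (g = A'r/n) between inner loops;
//    coordinates violating |g_j| > lambda join the set. Terminates only when
//    the screen finds no violation, so solutions agree with plain sweeps at
//    the stated tolerance.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

static double objective(const std::vector<double> &r,
                        const std::vector<double> &x,
                        int n, double lam) {
  double rss = 0.0;
  for (size_t i = 0; i < r.size(); ++i) rss += r[i] * r[i];
  double l1 = 0.0;
  for (size_t j = 0; j < x.size(); ++j) l1 += std::fabs(x[j]);
  return 0.5 * rss / n + lam * l1;
}

// one cyclic pass over the coordinates listed in idx; updates x and r in place
static void cd_sweep(const double *A, int n,
                     const std::vector<int> &idx,
                     std::vector<double> &x, std::vector<double> &r,
                     double lam) {
  const int inc = 1;
  for (size_t k = 0; k < idx.size(); ++k) {
    const int j = idx[k];
    const double *aj = A + static_cast<size_t>(n) * j;
    const double dot = F77_CALL(ddot)(&n, aj, &inc, r.data(), &inc);
    const double z = x[j] + dot / n;
    const double xnew = soft(z, lam);
    double d = xnew - x[j];
    if (d != 0.0) {
      d = -d;
      F77_CALL(daxpy)(&n, &d, aj, &inc, r.data(), &inc);
      x[j] = xnew;
    }
  }
}

// full gradient g = A'r / n through BLAS dgemv
static void full_gradient(const double *A, int n, int p,
                          const std::vector<double> &r,
                          std::vector<double> &g) {
  const double alpha = 1.0 / n, beta = 0.0;
  const int inc = 1;
  F77_CALL(dgemv)("T", &n, &p, &alpha, A, &n, r.data(), &inc,
                  &beta, g.data(), &inc FCONE);
}

// Solve one lambda. Returns sweeps used; sets *converged.
static int solve_one(const double *A, int n, int p, double lam,
                     std::vector<double> &x, std::vector<double> &r,
                     double tol, int max_sweeps, bool active_set,
                     bool *converged) {
  const double eps_obj = 1e-12;
  int sweeps = 0;
  *converged = false;

  if (!active_set) {
    std::vector<int> all(p);
    for (int j = 0; j < p; ++j) all[j] = j;
    double f_old = objective(r, x, n, lam);
    while (sweeps < max_sweeps) {
      cd_sweep(A, n, all, x, r, lam);
      ++sweeps;
      const double f_new = objective(r, x, n, lam);
      if (std::fabs(f_old - f_new) / std::max(std::fabs(f_old), eps_obj) < tol) {
        *converged = true;
        break;
      }
      f_old = f_new;
    }
    return sweeps;
  }

  // active-set mode
  std::vector<char> in_set(p, 0);
  std::vector<int> act;
  act.reserve(256);
  for (int j = 0; j < p; ++j)
    if (x[j] != 0.0) { in_set[j] = 1; act.push_back(j); }
  std::vector<double> g(p);
  const double kkt_slack = 1e-10;

  for (;;) {
    if (!act.empty()) {
      double f_old = objective(r, x, n, lam);
      while (sweeps < max_sweeps) {
        cd_sweep(A, n, act, x, r, lam);
        ++sweeps;
        const double f_new = objective(r, x, n, lam);
        if (std::fabs(f_old - f_new) / std::max(std::fabs(f_old), eps_obj) < tol)
          break;
        f_old = f_new;
      }
      if (sweeps >= max_sweeps) return sweeps; // not converged
    }
    // KKT screen over all coordinates
    full_gradient(A, n, p, r, g);
    bool any_violation = false;
    for (int j = 0; j < p; ++j) {
      if (!in_set[j] && std::fabs(g[j]) > lam + kkt_slack) {
        in_set[j] = 1;
        any_violation = true;
      }
    }
    if (!any_violation) {
      *converged = true;
      return sweeps;
    }
    act.clear();
    for (int j = 0; j < p; ++j)
      if (in_set[j]) act.push_back(j); // cyclic order preserved
  }
}

// [[Rcpp::export]]
List cd_solve_engine(NumericMatrix A, NumericVector y, double lam,
                     NumericVector x_init, double tol, int max_sweeps,
                     bool active_set) {
  const int n = A.nrow(), p = A.ncol();
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> r(y.begin(), y.end());
  const double *Ap = A.begin();
  // r = y - A x for a possibly nonzero warm start
  for (int j = 0; j < p; ++j) {
    if (x[j] != 0.0) {
      const double *aj = Ap + static_cast<size_t>(n) * j;
      for (int i = 0; i < n; ++i) r[i] -= x[j] * aj[i];
    }
  }
  bool conv = false;
  const int sw = solve_one(Ap, n, p, lam, x, r, tol, max_sweeps,
                           active_set, &conv);
  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["objective"] = objective(r, x, n, lam),
      _["sweeps"] = sw,
      _["converged"] = conv);
}

// [[Rcpp::export]]
List cd_path_engine(NumericMatrix A, NumericVector y, NumericVector lambdas,
                    double tol, int max_sweeps, bool active_set) {
  const int n = A.nrow(), p = A.ncol(), K = lambdas.size();
  const double *Ap = A.begin();
  std::vector<double> x(p, 0.0);
  std::vector<double> r(y.begin(), y.end());

  NumericMatrix coefs(p, K);
  NumericVector obj(K);
  IntegerVector sweeps(K);
  LogicalVector conv(K);

  for (int k = 0; k < K; ++k) {
    bool ck = false;
    sweeps[k] = solve_one(Ap, n, p, lambdas[k], x, r, tol, max_sweeps,
                          active_set, &ck);
    conv[k] = ck;
    obj[k] = objective(r, x, n, lambdas[k]);
    std::copy(x.begin(), x.end(), coefs.begin() + static_cast<size_t>(p) * k);
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["coefficients"] = coefs,
      _["objective"] = obj,
      _["sweeps"] = sweeps,
      _["converged"] = conv);
}
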