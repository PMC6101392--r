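#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// L1-regularized squared-hinge objective: ||w||_1 + C * sum_{b_i > 0} b_i^2,
// with margins b_i = 1 - y_i w.x_i supplied by the caller.
static double objective_from_margins(const std::vector<double>& w,
                                     const std::vector<double>& b,
                                     double C) {
  double l1 = 0.0, loss = 0.0;
  for (double wj : w) l1 += std::fabs(wj);
  for (double bi : b) if (bi > 0) loss += bi * bi;
  return l1 + C * loss;
}

// Closed-form minimizer of the one-variable piecewise quadratic
// |w_j + z| + d1 * z + (d2 / 2) * z^2 (subdifferential optimality).
static double solve_subproblem_cpp(double wj, double d1, double d2) {
  if (d1 + 1.0 <= d2 * wj) return -(d1 + 1.0) / d2;
  if (d1 - 1.0 >= d2 * wj) return -(d1 - 1.0) / d2;
  return -wj;
}

// Cyclic coordinate descent for the L1-regularized squared-hinge linear SVM.
// X: n_samples x n_genes (column-major, dense), y in {-1, +1}.
// Each coordinate takes a Newton-like step from the closed-form subproblem
// minimizer, safeguarded by Armijo backtracking on the true objective so the
// per-sweep objective trace is non-increasing. Margins are maintained
// incrementally and recomputed every 50 sweeps to bound floating-point drift.
// [[Rcpp::export(name = ".llsvm_cd_fit")]]
List llsvm_cd_fit(NumericMatrix X, NumericVector y, double C,
                  int max_sweeps, double tol, double beta, double sigma,
                  double hessian_floor, NumericVector w0) {
  const int n = X.nrow();
  const int p = X.ncol();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> b(n);

  auto recompute_margins = [&]() {
    for (int i = 0; i < n; ++i) {
      double dot = 0.0;
      for (int j = 0; j < p; ++j) dot += w[j] * X(i, j);
      b[i] = 1.0 - y[i] * dot;
    }
  };
  recompute_margins();

  std::vector<double> trace;
  trace.reserve(std::min(max_sweeps, 4096) + 1);
  trace.push_back(objective_from_margins(w, b, C));

  bool converged = false;
  int sweeps_run = 0;

  for (int k = 0; k < max_sweeps; ++k) {
    double max_step = 0.0;
    for (int j = 0; j < p; ++j) {
      // first and second derivative of the smooth part at z = 0,
      // restricted to the active set {i : b_i > 0}
      double d1 = 0.0, d2 = 0.0;
      for (int i = 0; i < n; ++i) {
        if (b[i] > 0) {
          const double xij = X(i, j);
          d1 += y[i] * xij * b[i];
          d2 += xij * xij;
        }
      }
      d1 *= -2.0 * C;
      d2 = std::max(2.0 * C * d2, hessian_floor);

      double zstar = solve_subproblem_cpp(w[j], d1, d2);
      if (zstar == 0.0) continue;

      // Armijo backtracking on the true objective:
      // accept step delta = beta^t * zstar when
      //   f(w + delta e_j) - f(w) <= sigma * beta^t * D,
      // D = d1 * zstar + |w_j + zstar| - |w_j|  (< 0 for a descent step).
      const double D = d1 * zstar + std::fabs(w[j] + zstar) - std::fabs(w[j]);
      double scale = 1.0;
      bool accepted = false;
      for (int t = 0; t <= 30; ++t, scale *= beta) {
        const double delta = scale * zstar;
        double dloss = 0.0;
        for (int i = 0; i < n; ++i) {
          const double bi_new = b[i] - delta * y[i] * X(i, j);
          if (b[i] > 0) dloss -= b[i] * b[i];
          if (bi_new > 0) dloss += bi_new * bi_new;
        }
        const double df = std::fabs(w[j] + delta) - std::fabs(w[j]) +
                          C * dloss;
        if (df <= sigma * scale * D && df <= 0.0) {
          for (int i = 0; i < n; ++i) b[i] -= delta * y[i] * X(i, j);
          w[j] += delta;
          if (std::fabs(delta) > max_step) max_step = std::fabs(delta);
          accepted = true;
          break;
        }
      }
      (void)accepted;  // rejected steps leave the coordinate unchanged
    }
    ++sweeps_run;
    if ((k + 1) % 50 == 0) recompute_margins();
    trace.push_back(objective_from_margins(w, b, C));
    if (max_step < tol) { converged = true; break; }
  }

  recompute_margins();
  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["objective_trace"] = NumericVector(trace.begin(), trace.end()),
    _["n_sweeps_run"] = sweeps_run,
    _["converged"] = converged,
    _["margins"] = NumericVector(b.begin(), b.end()));
}
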