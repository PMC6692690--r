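#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequential minimal optimisation for the two-class C-SVC dual with a
// precomputed kernel matrix.  Working-set selection is the maximal violating
// pair; the two-variable subproblem and the rho estimate follow the standard
// solver conventions, so decision values are
//   f(x) = sum_i alpha_i y_i K(x_i, x) - rho.
//
// K: n x n kernel matrix, y: labels in {-1, +1}, C: box constraint.
// Returns alpha (box-constrained, >= 0), rho, iteration count, and the final
// KKT violation gap.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C, double eps,
               int max_iter) {
  const int n = y.size();
  if (K.nrow() != n || K.ncol() != n)
    stop("kernel matrix does not match label vector");
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0); // gradient of the dual objective
  int iter = 0;
  double gap = R_PosInf;

  while (iter < max_iter) {
    // maximal violating pair
    double Gmax = R_NegInf, Gmin = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (i < 0 || j < 0 || gap < eps) break;

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    ++iter;
  }

  // intercept: average y*G over free support vectors, else midpoint of bounds
  double ub = R_PosInf, lb = R_NegInf, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free;
      sum_free += yG;
    }
  }
  const double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["gap"] = gap);
}
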