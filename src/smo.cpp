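#include <Rcpp.h>
using namespace Rcpp;

// SMO-style maximal-violating-pair solver for the soft-margin SVM dual:
//   min_a  0.5 a' Q a - e' a   s.t.  y' a = 0,  0 <= a_i <= C,
// with Q_ij = y_i y_j K_ij. Equivalent to maximizing
//   U(a) = sum_i a_i - 0.5 sum_ij a_i a_j y_i y_j K_ij.
// Gradient G_i = (Q a)_i - 1. Pair (i, j) chosen as the maximal KKT
// violation (first-order working-set selection); the two-variable
// subproblem is solved in closed form and clipped to the box.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol, int max_iter) {
  const int n = K.nrow();
  NumericVector alpha(n, 0.0);
  NumericVector G(n, -1.0);   // gradient at alpha = 0

  int iter = 0;
  double viol = R_PosInf;
  while (iter < max_iter) {
    // i in I_up maximizing -y_i G_i; j in I_low minimizing -y_j G_j
    double gmax = R_NegInf, gmin = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > gmax)  { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    viol = gmax - gmin;
    if (i < 0 || j < 0 || viol < tol) break;

    // direction d_i = y_i, d_j = -y_j keeps y'a constant; optimal step
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double s = viol / quad;   // (-y_i G_i) - (-y_j G_j) = y_j G_j - y_i G_i

    // box limits on s from 0 <= alpha +/- <= C
    double smax = s;
    if (y[i] > 0) smax = std::min(smax, C - alpha[i]);
    else          smax = std::min(smax, alpha[i]);
    if (y[j] > 0) smax = std::min(smax, alpha[j]);
    else          smax = std::min(smax, C - alpha[j]);
    s = std::max(0.0, std::min(s, smax));
    if (s <= 0) break;  // no feasible progress

    alpha[i] += y[i] * s;
    alpha[j] -= y[j] * s;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * s * (K(t, i) - K(t, j));
    ++iter;
  }

  // offset: average of y_i - F_i over free support vectors,
  // F_i = sum_j alpha_j y_j K_ij = y_i (G_i + 1)
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) {
      double F = y[t] * (G[t] + 1.0);
      bsum += y[t] - F;
      ++nfree;
    }
  }
  double b;
  if (nfree > 0) {
    b = bsum / nfree;
  } else {
    double up = R_PosInf, lo = R_NegInf;
    for (int t = 0; t < n; ++t) {
      double F = y[t] * (G[t] + 1.0);
      double c = y[t] - F;
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up)  up = std::min(up, c);
      if (in_low) lo = std::max(lo, c);
    }
    b = (std::isfinite(up) && std::isfinite(lo)) ? (up + lo) / 2.0 : 0.0;
  }

  return List::create(_["alpha"] = alpha, _["b"] = b, _["iterations"] = iter,
                      _["max_violation"] = viol,
                      _["converged"] = (viol < tol));
}
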