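#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kernel matrix between rows of X1 (n1 x d) and X2 (n2 x d).
// kernel: 0 = rbf (gamma = 1/(2 sigma^2)), 1 = linear, 2 = poly (x.y + 1)^3
// [[Rcpp::export]]
NumericMatrix kernel_matrix(NumericMatrix X1, NumericMatrix X2,
                            int kernel, double gamma) {
  int n1 = X1.nrow(), n2 = X2.nrow(), d = X1.ncol();
  NumericMatrix K(n1, n2);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double acc = 0.0;
      if (kernel == 0) {
        for (int k = 0; k < d; ++k) {
          double diff = X1(i, k) - X2(j, k);
          acc += diff * diff;
        }
        K(i, j) = std::exp(-gamma * acc);
      } else {
        for (int k = 0; k < d; ++k) acc += X1(i, k) * X2(j, k);
        K(i, j) = (kernel == 1) ? acc : std::pow(acc + 1.0, 3.0);
      }
    }
  }
  return K;
}

// SMO for the soft-margin SVM dual:
//   min_a 0.5 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
// Working-set selection by maximal violating pair; deterministic.
// Returns alpha, bias b, iteration count.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_iter = 20000) {
  int n = K.nrow();
  NumericVector alpha(n, 0.0);
  // gradient of the dual objective: g_i = (Q a)_i - 1; starts at -1
  NumericVector g(n, -1.0);
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // i: argmax over I_up of -y_t g_t ; j: argmin over I_low of -y_t g_t
    int i = -1, j = -1;
    double gmax = -R_PosInf, gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * g[t];
      bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (up && v > gmax)  { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // second derivative along the feasible direction (a_i += y_i d,
    // a_j -= y_j d): always K_ii + K_jj - 2 K_ij, label-free
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double delta = (gmax - gmin) / quad;

    double ai_old = alpha[i], aj_old = alpha[j];
    // feasible step range keeping both multipliers in [0, C] and the
    // equality constraint intact
    double lo, hi;
    if (y[i] > 0) { lo = -ai_old;    hi = C - ai_old; }
    else          { lo = ai_old - C; hi = ai_old; }
    if (y[j] > 0) { lo = std::max(lo, aj_old - C); hi = std::min(hi, aj_old); }
    else          { lo = std::max(lo, -aj_old);    hi = std::min(hi, C - aj_old); }
    if (delta > hi) delta = hi;
    if (delta < lo) delta = lo;
    double ai = ai_old + y[i] * delta;
    double aj = aj_old - y[j] * delta;

    double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) break;
    for (int t = 0; t < n; ++t)
      g[t] += y[t] * (y[i] * dai * K(i, t) + y[j] * daj * K(j, t));
    alpha[i] = ai; alpha[j] = aj;
  }

  // bias: average of -y_t g_t over free support vectors, else midpoint
  double bsum = 0.0; int nfree = 0;
  double ub = R_PosInf, lb = R_NegInf;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * g[t];
    bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { bsum += v; ++nfree; }
    if (up && v < ub) ub = v;
    if (low && v > lb) lb = v;
  }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else if (R_finite(ub) && R_finite(lb)) b = (ub + lb) / 2.0;
  else b = 0.0;

  return List::create(_["alpha"] = alpha, _["b"] = b, _["iter"] = iter);
}

// decision values f(x) = sum_i alpha_i y_i K(x_i, x) + b for test kernel
// Ktest: n_train x n_test
// [[Rcpp::export]]
NumericVector svm_decision(NumericMatrix Ktest, NumericVector alpha,
                           NumericVector y, double b) {
  int n = Ktest.nrow(), m = Ktest.ncol();
  NumericVector f(m, b);
  for (int i = 0; i < n; ++i) {
    double ay = alpha[i] * y[i];
    if (ay == 0.0) continue;
    for (int j = 0; j < m; ++j) f[j] += ay * Ktest(i, j);
  }
  return f;
}
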