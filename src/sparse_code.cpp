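#include <Rcpp.h>
using namespace Rcpp;

// Lasso coding of patches against a fixed dictionary by cyclic coordinate
// descent with soft-thresholding. Objective per patch (no 1/2 factor):
//   ||x - Phi c||_2^2 + lambda * ||c||_1
// X: n x d patches (rows), Phi: d x m dictionary atoms (columns),
// C0: n x m warm-start codes. Converges when the largest coefficient change
// in a sweep falls below tol.
// [[Rcpp::export]]
NumericMatrix encode_cd(const NumericMatrix& X, const NumericMatrix& Phi,
                        const NumericMatrix& C0, double lambda,
                        int max_sweeps, double tol) {
  const int n = X.nrow(), d = X.ncol(), m = Phi.ncol();
  NumericMatrix C = clone(C0);

  // Gram matrix G = Phi^T Phi (m x m) and atom norms
  std::vector<double> G(m * m);
  for (int a = 0; a < m; ++a)
    for (int b = a; b < m; ++b) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += Phi(k, a) * Phi(k, b);
      G[a * m + b] = s;
      G[b * m + a] = s;
    }

  const double thr = lambda / 2.0;  // soft threshold for the unhalved objective
  std::vector<double> b(m);

  for (int i = 0; i < n; ++i) {
    // b = Phi^T x_i
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += Phi(k, j) * X(i, k);
      b[j] = s;
    }
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double max_delta = 0.0;
      for (int j = 0; j < m; ++j) {
        const double gjj = G[j * m + j];
        if (gjj <= 0.0) { continue; }  // zero atom never activates
        // rho = b_j - sum_{k != j} G_jk c_k  (partial residual correlation)
        double rho = b[j];
        for (int k = 0; k < m; ++k)
          if (k != j && C(i, k) != 0.0) rho -= G[j * m + k] * C(i, k);
        double cj;
        if (rho > thr)       cj = (rho - thr) / gjj;
        else if (rho < -thr) cj = (rho + thr) / gjj;
        else                 cj = 0.0;
        double delta = std::fabs(cj - C(i, j));
        if (delta > max_delta) max_delta = delta;
        C(i, j) = cj;
      }
      if (max_delta < tol) break;
    }
  }
  return C;
}

// Eq.-style sparse-coding objective: sum_i ||x_i - Phi c_i||^2 + lambda |C|_1
// [[Rcpp::export]]
double sc_objective_cpp(const NumericMatrix& X, const NumericMatrix& Phi,
                        const NumericMatrix& C, double lambda) {
  const int n = X.nrow(), d = X.ncol(), m = Phi.ncol();
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) {
      double r = X(i, k);
      for (int j = 0; j < m; ++j)
        if (C(i, j) != 0.0) r -= C(i, j) * Phi(k, j);
      obj += r * r;
    }
    for (int j = 0; j < m; ++j) obj += lambda * std::fabs(C(i, j));
  }
  return obj;
}
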