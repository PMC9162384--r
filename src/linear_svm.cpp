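#include <Rcpp.h>
using namespace Rcpp;

// L2-regularized, L2-loss (squared hinge) linear SVM -- the standard
// LIBLINEAR formulation:
//   min_w f(w) = 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x~_i)^2
// with the intercept folded into w via an augmented constant feature
// (x~ = [x, 1]), so the intercept is regularized. f is differentiable
// with a piecewise-linear gradient; we minimize it by a damped Newton
// method on the generalized Hessian H = I + 2C X_A' X_A (A = samples with
// positive margin violation), solving each step by Cholesky. The feature
// dimension is small in this package (a handful of regional metrics plus
// incident edges), so each iteration is O(n p^2) and the method converges
// in a few dozen iterations for every C on the grid. The algorithm is
// entirely deterministic: no sampling, no visiting order.
//
// Convergence: ||grad|| <= tol * max(1, ||grad at w = 0||).

namespace {

struct Newton {
  const NumericMatrix& X;   // all samples, augmented
  std::vector<int> rows;    // active sample subset
  std::vector<double> y;    // labels for the subset
  std::vector<double> w;
  bool converged;
  int iters;

  Newton(const NumericMatrix& X_) : X(X_), converged(false), iters(0) {}

  double objective(const std::vector<double>& wv, double C) const {
    const int p = X.ncol();
    double obj = 0.0;
    for (int j = 0; j < p; ++j) obj += 0.5 * wv[j] * wv[j];
    for (size_t k = 0; k < rows.size(); ++k) {
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += wv[j] * X(rows[k], j);
      double m = 1.0 - y[k] * wx;
      if (m > 0) obj += C * m * m;
    }
    return obj;
  }

  void solve(double C, double tol, int max_iter) {
    const int n = (int)rows.size();
    const int p = X.ncol();
    if ((int)w.size() != p) w.assign(p, 0.0);
    std::vector<double> g(p), d(p), H((size_t)p * p);
    std::vector<double> wx(n);

    // gradient norm at w = 0 sets the convergence scale
    double g0norm = 0.0;
    {
      std::vector<double> g0(p, 0.0);
      for (int k = 0; k < n; ++k)
        for (int j = 0; j < p; ++j)
          g0[j] -= 2.0 * C * y[k] * X(rows[k], j);
      for (int j = 0; j < p; ++j) g0norm += g0[j] * g0[j];
      g0norm = std::sqrt(g0norm);
      if (g0norm < 1.0) g0norm = 1.0;
    }

    converged = false;
    int it;
    for (it = 0; it < max_iter; ++it) {
      // gradient and generalized Hessian over the violating set
      std::fill(g.begin(), g.end(), 0.0);
      std::fill(H.begin(), H.end(), 0.0);
      for (int j = 0; j < p; ++j) {
        g[j] = w[j];
        H[(size_t)j * p + j] = 1.0;
      }
      for (int k = 0; k < n; ++k) {
        const int i = rows[k];
        double s = 0.0;
        for (int j = 0; j < p; ++j) s += w[j] * X(i, j);
        wx[k] = s;
        double m = 1.0 - y[k] * s;
        if (m > 0) {
          for (int j = 0; j < p; ++j) {
            double xj = X(i, j);
            g[j] -= 2.0 * C * y[k] * m * xj;
            for (int l = j; l < p; ++l)
              H[(size_t)j * p + l] += 2.0 * C * xj * X(i, l);
          }
        }
      }
      double gnorm = 0.0;
      for (int j = 0; j < p; ++j) gnorm += g[j] * g[j];
      gnorm = std::sqrt(gnorm);
      if (gnorm <= tol * g0norm) { converged = true; break; }

      // Cholesky H = L L' (upper triangle stored), solve H d = -g
      for (int j = 0; j < p; ++j)
        for (int l = 0; l < j; ++l)
          H[(size_t)j * p + l] = H[(size_t)l * p + j];
      for (int j = 0; j < p; ++j) {
        for (int l = 0; l <= j; ++l) {
          double s = H[(size_t)j * p + l];
          for (int m2 = 0; m2 < l; ++m2)
            s -= H[(size_t)j * p + m2] * H[(size_t)l * p + m2];
          if (l == j) {
            if (s <= 0) s = 1e-12;
            H[(size_t)j * p + j] = std::sqrt(s);
          } else {
            H[(size_t)j * p + l] = s / H[(size_t)l * p + l];
          }
        }
      }
      for (int j = 0; j < p; ++j) {          // L u = -g
        double s = -g[j];
        for (int l = 0; l < j; ++l) s -= H[(size_t)j * p + l] * d[l];
        d[j] = s / H[(size_t)j * p + j];
      }
      for (int j = p - 1; j >= 0; --j) {     // L' d = u
        double s = d[j];
        for (int l = j + 1; l < p; ++l) s -= H[(size_t)l * p + j] * d[l];
        d[j] = s / H[(size_t)j * p + j];
      }

      // Armijo backtracking (full Newton step nearly always accepted)
      double f0 = objective(w, C);
      double gd = 0.0;
      for (int j = 0; j < p; ++j) gd += g[j] * d[j];
      double step = 1.0;
      std::vector<double> wn(p);
      for (int ls = 0; ls < 40; ++ls) {
        for (int j = 0; j < p; ++j) wn[j] = w[j] + step * d[j];
        if (objective(wn, C) <= f0 + 0.01 * step * gd) break;
        step *= 0.5;
      }
      for (int j = 0; j < p; ++j) w[j] += step * d[j];
    }
    iters = it;
  }

  double decision(int row) const {
    double s = 0.0;
    for (int j = 0; j < X.ncol(); ++j) s += w[j] * X(row, j);
    return s;
  }
};

} // namespace

// [[Rcpp::export]]
List svm_linear_newton(NumericMatrix X, NumericVector y, double C,
                       double tol = 1e-10, int max_iter = 200,
                       Nullable<NumericVector> w0 = R_NilValue) {
  const int n = X.nrow();
  Newton s(X);
  s.rows.resize(n);
  s.y.resize(n);
  for (int i = 0; i < n; ++i) { s.rows[i] = i; s.y[i] = y[i]; }
  if (w0.isNotNull()) {
    NumericVector w0v(w0);
    if (w0v.size() != X.ncol()) stop("w0 must have one entry per column");
    s.w.assign(w0v.begin(), w0v.end());
  }
  s.solve(C, tol, max_iter);
  return List::create(_["w"] = NumericVector(s.w.begin(), s.w.end()),
                      _["iters"] = s.iters,
                      _["converged"] = s.converged);
}

// Inner leave-one-out model selection for one outer fold: for every C in
// the grid, fit on each (n-1)-sample subset (warm-started from a base fit
// on all n samples at that C) and score the left-out sample. Returns the
// inner-validation accuracy per C. X is the standardized, augmented
// outer-training matrix.
//
// [[Rcpp::export]]
NumericVector svm_inner_loocv(NumericMatrix X, NumericVector y,
                              NumericVector c_grid,
                              double tol = 1e-10, int max_iter = 200) {
  const int n = X.nrow();
  NumericVector acc(c_grid.size());

  for (int ci = 0; ci < c_grid.size(); ++ci) {
    const double C = c_grid[ci];
    Newton base(X);
    base.rows.resize(n);
    base.y.resize(n);
    for (int i = 0; i < n; ++i) { base.rows[i] = i; base.y[i] = y[i]; }
    base.solve(C, tol, max_iter);

    int good = 0;
    Newton sub(X);
    sub.rows.resize(n - 1);
    sub.y.resize(n - 1);
    for (int j = 0; j < n; ++j) {
      int m = 0;
      bool pos = false, neg = false;
      for (int i = 0; i < n; ++i) {
        if (i == j) continue;
        sub.rows[m] = i;
        sub.y[m] = y[i];
        if (y[i] > 0) pos = true; else neg = true;
        ++m;
      }
      if (!pos || !neg)
        stop("inner training fold collapsed to a single class");
      sub.w = base.w;   // warm start from the all-sample fit
      sub.solve(C, tol, max_iter);
      double d = sub.decision(j);
      if ((d >= 0.0 ? 1.0 : -1.0) == y[j]) ++good;
    }
    acc[ci] = (double)good / n;
  }
  return acc;
}
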