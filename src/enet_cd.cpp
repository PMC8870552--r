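#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net with per-feature penalty
// factors, over a decreasing lambda path with warm starts.
//
// Minimizes (1/2n)||y - X b||^2
//           + lambda * sum_j pf_j * (alpha |b_j| + (1-alpha)/2 b_j^2).
// X must be standardized so that each column has mean 0 and (1/n) x_j'x_j
// = 1; y must be centered. Update:
//   b_j <- S(x_j'r/n + b_j, lambda*alpha*pf_j) / (1 + lambda*(1-alpha)*pf_j)
// Convergence: max absolute coefficient change within a sweep < tol.
// [[Rcpp::export]]
NumericMatrix enet_cd_path(const NumericMatrix& X, const NumericVector& y,
                           const NumericVector& pf, double alpha,
                           const NumericVector& lambdas,
                           double tol = 1e-7, int max_sweeps = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix B(p, L);
  std::vector<double> beta(p, 0.0);
  std::vector<double> r(y.begin(), y.end());
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int sweep = 0;
    for (; sweep < max_sweeps; ++sweep) {
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        const double* xj = &X(0, j);
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
        const double z = xr / n + beta[j];
        const double bj = soft(z, lam * alpha * pf[j]) /
                          (1.0 + lam * (1.0 - alpha) * pf[j]);
        const double d = bj - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
          beta[j] = bj;
          const double ad = d < 0 ? -d : d;
          if (ad > maxd) maxd = ad;
        }
      }
      if (maxd < tol) break;
    }
    if (sweep >= max_sweeps)
      stop("coordinate descent did not converge (lambda=%g, p=%d, n=%d)",
           lam, p, n);
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}

// K-fold cross-validated MSE over a lambda path. For each fold, the
// training rows are standardized and the elastic-net path is fit by
// covariance-update coordinate descent (gradients maintained from the
// p x p Gram matrix, O(p) per coordinate update -- cis designs are
// narrow), with warm starts along the path; validation MSE is
// accumulated per lambda on the raw scale. Returns the per-lambda mean
// of fold MSEs.
// [[Rcpp::export]]
NumericVector cv_mse_path_cpp(const NumericMatrix& X, const NumericVector& y,
                              const NumericVector& pf, double alpha,
                              const IntegerVector& folds,
                              const NumericVector& lambdas,
                              double tol = 1e-7, int max_sweeps = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  int K = 0;
  for (int i = 0; i < n; ++i) if (folds[i] > K) K = folds[i];
  NumericVector mse(L);
  std::vector<int> fold_n(K + 1, 0);
  for (int i = 0; i < n; ++i) ++fold_n[folds[i]];

  std::vector<double> Xtr(n * p), beta(p), mu(p), sd(p), w(p), q(p),
      S(p * p), grad(p);
  for (int f = 1; f <= K; ++f) {
    const int ntr = n - fold_n[f], nva = fold_n[f];
    if (ntr < 2 || nva < 1) continue;
    // training means / sds
    double ybar = 0.0;
    for (int j = 0; j < p; ++j) { mu[j] = 0.0; sd[j] = 0.0; }
    for (int i = 0; i < n; ++i) {
      if (folds[i] == f) continue;
      ybar += y[i];
      for (int j = 0; j < p; ++j) mu[j] += X(i, j);
    }
    ybar /= ntr;
    for (int j = 0; j < p; ++j) mu[j] /= ntr;
    for (int i = 0; i < n; ++i) {
      if (folds[i] == f) continue;
      for (int j = 0; j < p; ++j) {
        const double d = X(i, j) - mu[j];
        sd[j] += d * d;
      }
    }
    for (int j = 0; j < p; ++j) sd[j] = std::sqrt(sd[j] / ntr);
    // standardized training design (column-major)
    int row = 0;
    for (int i = 0; i < n; ++i) {
      if (folds[i] == f) continue;
      for (int j = 0; j < p; ++j)
        Xtr[j * ntr + row] = sd[j] > 0 ? (X(i, j) - mu[j]) / sd[j] : 0.0;
      ++row;
    }
    // Gram matrix S = X'X/ntr and q = X'y/ntr (y centered)
    for (int j = 0; j < p; ++j) {
      const double* xj = &Xtr[j * ntr];
      double qj = 0.0;
      row = 0;
      for (int i = 0; i < n; ++i) {
        if (folds[i] == f) continue;
        qj += xj[row] * (y[i] - ybar);
        ++row;
      }
      q[j] = qj / ntr;
      for (int k = 0; k <= j; ++k) {
        const double* xk = &Xtr[k * ntr];
        double s = 0.0;
        for (int i = 0; i < ntr; ++i) s += xj[i] * xk[i];
        S[j * p + k] = S[k * p + j] = s / ntr;
      }
    }
    std::fill(beta.begin(), beta.end(), 0.0);
    for (int j = 0; j < p; ++j) grad[j] = q[j];  // q - S beta at beta = 0
    for (int l = 0; l < L; ++l) {
      const double lam = lambdas[l];
      int sweep = 0;
      for (; sweep < max_sweeps; ++sweep) {
        double maxd = 0.0;
        for (int j = 0; j < p; ++j) {
          if (sd[j] <= 0) continue;
          const double z = grad[j] + beta[j];
          const double bj = soft(z, lam * alpha * pf[j]) /
                            (1.0 + lam * (1.0 - alpha) * pf[j]);
          const double d = bj - beta[j];
          if (d != 0.0) {
            const double* Sj = &S[j * p];
            for (int k = 0; k < p; ++k) grad[k] -= Sj[k] * d;
            beta[j] = bj;
            const double ad = d < 0 ? -d : d;
            if (ad > maxd) maxd = ad;
          }
        }
        if (maxd < tol) break;
      }
      if (sweep >= max_sweeps)
        stop("coordinate descent did not converge in inner CV");
      // validation MSE on the raw scale
      double icept = ybar;
      for (int j = 0; j < p; ++j) {
        w[j] = sd[j] > 0 ? beta[j] / sd[j] : 0.0;
        icept -= w[j] * mu[j];
      }
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        if (folds[i] != f) continue;
        double pred = icept;
        for (int j = 0; j < p; ++j) pred += w[j] * X(i, j);
        const double e = y[i] - pred;
        sse += e * e;
      }
      mse[l] += sse / nva / K;
    }
  }
  return mse;
}
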