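#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gaussian part of the log joint of each causality configuration, computed
// in the causal subspace (intercept always active):
//   -k/2 * log(sigma2) - 1/2 * log det Q + 1/2 * b_A' Q^{-1} b_A
// with Q = M[A,A] + diag(intercept_prec, 1/sigma2, ...), A = {0} u config.
//
// Configurations arrive flattened: `configs` holds concatenated 1-based SNP
// indices (within the block, excluding the intercept) and `offsets` the
// 0-based start of each configuration (length n_configs + 1). The per-config
// subproblem is tiny (m = k+1 <= 33), so the Cholesky factorization is done
// in a stack buffer without allocations.
static const int MAX_ACTIVE = 33;

// [[Rcpp::export]]
arma::vec config_gauss_terms(const arma::mat& M, const arma::vec& b,
                             const IntegerVector& configs,
                             const IntegerVector& offsets,
                             double sigma2, double intercept_prec) {
  const int ncfg = offsets.size() - 1;
  const int dim = M.n_rows;
  const double logs2 = std::log(sigma2);
  const double s2inv = 1.0 / sigma2;
  const double* Mp = M.memptr();
  const double* bp = b.memptr();
  arma::vec out(ncfg);

  double Q[MAX_ACTIVE * MAX_ACTIVE];
  double z[MAX_ACTIVE];
  int act[MAX_ACTIVE];

  for (int c = 0; c < ncfg; ++c) {
    const int s = offsets[c], e = offsets[c + 1];
    const int m = e - s + 1;
    if (m > MAX_ACTIVE) stop("configuration size exceeds %d", MAX_ACTIVE - 1);
    act[0] = 0;
    for (int j = s; j < e; ++j) act[j - s + 1] = configs[j];
    for (int j = 0; j < m; ++j) {
      const double* Mcol = Mp + (size_t)act[j] * dim;
      for (int i = j; i < m; ++i) Q[j * m + i] = Mcol[act[i]];
      z[j] = bp[act[j]];
    }
    Q[0] += intercept_prec;
    for (int j = 1; j < m; ++j) Q[j * m + j] += s2inv;

    // in-place lower Cholesky of Q, log det, and forward solve of z
    double logdet = 0.0;
    bool ok = true;
    for (int j = 0; j < m && ok; ++j) {
      double d = Q[j * m + j];
      for (int r = 0; r < j; ++r) {
        const double l = Q[r * m + j];
        d -= l * l;
      }
      if (d <= 0.0) { ok = false; break; }
      const double ljj = std::sqrt(d);
      logdet += 2.0 * std::log(ljj);
      Q[j * m + j] = ljj;
      for (int i = j + 1; i < m; ++i) {
        double v = Q[j * m + i];
        for (int r = 0; r < j; ++r) v -= Q[r * m + i] * Q[r * m + j];
        Q[j * m + i] = v / ljj;
      }
      double zv = z[j];
      for (int r = 0; r < j; ++r) zv -= Q[r * m + j] * z[r];
      z[j] = zv / ljj;
    }
    if (!ok) {
      stop("configuration %d: causal-subspace precision not positive "
           "definite (sigma too large relative to the data precision)", c + 1);
    }
    double quad = 0.0;
    for (int j = 0; j < m; ++j) quad += z[j] * z[j];
    out[c] = -0.5 * logdet + 0.5 * quad - 0.5 * (m - 1) * logs2;
  }
  return out;
}
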