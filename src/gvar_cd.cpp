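#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft_thr(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Coordinate descent for the lag-1 coefficient matrix B with the residual
// precision K held fixed.  Minimises, in Gram form,
//   (1/2) tr( K * S_E(B) ) + lambda * sum_ij |B(i,j)|
// with S_E(B) = Syy - B*C - (B*C)' + B*G*B', G = X'X/n, C = X'Y/n.
// Convention: B(i,j) is the effect of predictor j at t-1 on outcome i at t.
// The update keeps M = X'E/n = C - G*B' current, so each coordinate costs
// O(p) independent of n.
// [[Rcpp::export]]
arma::mat cd_beta(const arma::mat& G, const arma::mat& C, const arma::mat& K,
                  arma::mat B, double lambda, double tol, int max_sweeps) {
  const arma::uword p = G.n_rows;
  arma::mat M = C - G * B.t();
  for (int s = 0; s < max_sweeps; ++s) {
    double maxd = 0.0;
    for (arma::uword i = 0; i < p; ++i) {
      for (arma::uword j = 0; j < p; ++j) {
        const double denom = K(i, i) * G(j, j);
        if (denom <= 0.0) continue; // degenerate predictor: leave coefficient at 0
        const double mk = arma::dot(M.row(j), K.col(i));
        const double z = B(i, j) + mk / denom;
        const double bn = soft_thr(z, lambda / denom);
        const double d = bn - B(i, j);
        if (d != 0.0) {
          B(i, j) = bn;
          M.col(i) -= G.col(j) * d;
          const double ad = std::abs(d);
          if (ad > maxd) maxd = ad;
        }
      }
    }
    if (maxd < tol) break;
  }
  return B;
}

// Blockwise-coordinate-descent graphical lasso (Friedman-style) with the
// penalty applied to off-diagonal precision entries only.  Returns the
// penalised covariance W and precision K recovered from the final block
// solutions, so soft-thresholded zeros are exact.
// [[Rcpp::export]]
List glasso_cd(const arma::mat& S, double rho, double tol, int max_iter) {
  const arma::uword p = S.n_rows;
  arma::mat W = S;
  arma::mat Beta(p, p, arma::fill::zeros); // column j holds block-j lasso coefs
  bool converged = false;
  int iter = 0;

  std::vector<arma::uvec> rest(p);
  for (arma::uword j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    arma::uword c = 0;
    for (arma::uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    rest[j] = idx;
  }

  for (iter = 0; iter < max_iter; ++iter) {
    double maxd = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      const arma::uvec& idx = rest[j];
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec beta = Beta.col(j);
      beta = beta.elem(idx);
      // inner lasso: min (1/2) b'W11 b - s12'b + rho*|b|_1
      for (int t = 0; t < 1000; ++t) {
        double mdi = 0.0;
        for (arma::uword k = 0; k < p - 1; ++k) {
          const double r = s12(k) - arma::dot(W11.row(k), beta) +
            W11(k, k) * beta(k);
          const double bn = soft_thr(r, rho) / W11(k, k);
          const double d = bn - beta(k);
          if (d != 0.0) {
            beta(k) = bn;
            const double ad = std::abs(d);
            if (ad > mdi) mdi = ad;
          }
        }
        if (mdi < 0.1 * tol) break;
      }
      arma::vec w12 = W11 * beta;
      for (arma::uword k = 0; k < p - 1; ++k) {
        const double d = std::abs(w12(k) - W(idx(k), j));
        if (d > maxd) maxd = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        Beta(idx(k), j) = beta(k);
      }
    }
    if (maxd < tol) { converged = true; ++iter; break; }
  }

  arma::mat K(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    const arma::uvec& idx = rest[j];
    arma::vec beta = Beta.col(j);
    beta = beta.elem(idx);
    arma::vec w12 = W.col(j);
    w12 = w12.elem(idx);
    const double denom = W(j, j) - arma::dot(w12, beta);
    const double kjj = 1.0 / denom;
    K(j, j) = kjj;
    for (arma::uword k = 0; k < p - 1; ++k) K(idx(k), j) = -beta(k) * kjj;
  }
  K = 0.5 * (K + K.t());
  return List::create(_["K"] = K, _["W"] = W,
                      _["iterations"] = iter, _["converged"] = converged);
}
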