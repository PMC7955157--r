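// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Greedy left-to-right LD pruning within one chromosome.
// g: samples x M dosage matrix (NA allowed), pos: bp positions (sorted).
// A later marker is pruned when its squared Pearson correlation with a
// retained anchor within window_bp exceeds r2max. Pairs are computed over
// samples called in both markers; zero-variance pairs give r^2 = 0.
// [[Rcpp::export]]
LogicalVector ld_prune_chrom(NumericMatrix g, IntegerVector pos,
                             double window_bp, int step, double r2max) {
  const int n = g.nrow(), m = g.ncol();
  LogicalVector keep(m, true);
  for (int i = 0; i < m; i += step) {
    if (!keep[i]) continue;
    for (int j = i + 1; j < m && pos[j] - pos[i] <= window_bp; ++j) {
      if (!keep[j]) continue;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int cnt = 0;
      for (int s = 0; s < n; ++s) {
        const double x = g(s, i), y = g(s, j);
        if (ISNAN(x) || ISNAN(y)) continue;
        sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
        ++cnt;
      }
      if (cnt < 2) continue;
      const double vx = sxx - sx * sx / cnt;
      const double vy = syy - sy * sy / cnt;
      if (vx <= 0 || vy <= 0) continue;  // undefined r^2 -> never pruned
      const double cxy = sxy - sx * sy / cnt;
      if (cxy * cxy / (vx * vy) > r2max) keep[j] = false;
    }
  }
  return keep;
}

// Bayes factors (deciban) for the Gaussian standardized-covariate model.
// u: P x M standardized sample frequencies; d: P x M per-population sampling
// variances (on the standardized scale); omega: P x P covariance of
// standardized population frequencies; z: P x C standardized covariates;
// beta_grid: quadrature nodes of the uniform effect-size prior.
// For SNP s with Sigma = omega + diag(d_s), the data-dependent part of the
// log-likelihood at effect beta is beta * b_c - beta^2 * q_c / 2 with
// b_c = z_c' Sigma^-1 u_s and q_c = z_c' Sigma^-1 z_c; the Gaussian
// normalization and the u' Sigma^-1 u term cancel between H1 and H0, so
// BF = mean_over_grid exp(beta b - beta^2 q / 2).
// [[Rcpp::export]]
arma::mat bf_db_kernel(const arma::mat& u, const arma::mat& d,
                       const arma::mat& omega, const arma::mat& z,
                       const arma::vec& beta_grid) {
  const arma::uword P = u.n_rows, M = u.n_cols, C = z.n_cols,
                    G = beta_grid.n_elem;
  arma::mat out(M, C);
  out.fill(arma::datum::nan);
  const arma::vec bg2 = 0.5 * arma::square(beta_grid);
  const double logG = std::log(static_cast<double>(G));
  for (arma::uword s = 0; s < M; ++s) {
    if (!u.col(s).is_finite()) continue;
    arma::mat Sigma = omega;
    Sigma.diag() += d.col(s);
    arma::mat rhs(P, C + 1);
    rhs.col(0) = u.col(s);
    rhs.cols(1, C) = z;
    arma::mat X;
    if (!arma::solve(X, Sigma, rhs, arma::solve_opts::likely_sympd))
      continue;  // leaves NaN: singular covariance at this site
    for (arma::uword c = 0; c < C; ++c) {
      const double b = arma::dot(z.col(c), X.col(0));
      const double q = arma::dot(z.col(c), X.col(c + 1));
      arma::vec lp = beta_grid * b - bg2 * q;
      const double mx = lp.max();
      const double lbf = mx + std::log(arma::accu(arma::exp(lp - mx))) - logG;
      out(s, c) = 10.0 * lbf / std::log(10.0);
    }
  }
  return out;
}
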