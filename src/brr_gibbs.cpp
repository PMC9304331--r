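// Gibbs sampler for Bayesian ridge regression: y = 1*mu + Z*gamma + e with
// gamma_j ~ N(0, s2g) iid, s2g and s2e with scaled-inverse-chi-square
// hyperpriors. Marker effects are sampled one at a time against a running
// residual (the standard single-site conjugate scheme). Uses R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List brr_gibbs_cpp(const arma::vec& y, const arma::mat& Z, int n_iter,
                   int burnin, double df_g, double S_g, double df_e,
                   double S_e, bool fix_var, double s2g_fix, double s2e_fix,
                   double s2g_init, double s2e_init) {
  const int n = Z.n_rows;
  const int p = Z.n_cols;
  arma::vec zz(p);
  for (int j = 0; j < p; ++j) zz[j] = arma::dot(Z.col(j), Z.col(j));

  double mu = arma::mean(y);
  arma::vec gamma(p, arma::fill::zeros);
  arma::vec e = y - mu;
  double s2g = fix_var ? s2g_fix : s2g_init;
  double s2e = fix_var ? s2e_fix : s2e_init;

  double mu_acc = 0.0, s2g_acc = 0.0, s2e_acc = 0.0;
  arma::vec g_acc(p, arma::fill::zeros);
  arma::vec fit_acc(n, arma::fill::zeros);
  int n_keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double mu_new = R::rnorm(arma::mean(e) + mu, std::sqrt(s2e / n));
    e += (mu - mu_new);
    mu = mu_new;

    // marker effects, single-site updates
    const double lambda = s2e / s2g;
    for (int j = 0; j < p; ++j) {
      if (zz[j] <= 0.0) { gamma[j] = R::rnorm(0.0, std::sqrt(s2g)); continue; }
      const double c = zz[j] + lambda;
      const double rhs = arma::dot(Z.col(j), e) + zz[j] * gamma[j];
      const double gnew = R::rnorm(rhs / c, std::sqrt(s2e / c));
      e -= Z.col(j) * (gnew - gamma[j]);
      gamma[j] = gnew;
    }

    if (!fix_var) {
      s2g = (df_g * S_g + arma::dot(gamma, gamma)) / R::rchisq(df_g + p);
      s2e = (df_e * S_e + arma::dot(e, e)) / R::rchisq(df_e + n);
    }

    if (it >= burnin) {
      ++n_keep;
      mu_acc += mu;
      s2g_acc += s2g;
      s2e_acc += s2e;
      g_acc += gamma;
      fit_acc += y - e;
    }
  }

  return List::create(
      _["mu"] = mu_acc / n_keep, _["gamma"] = g_acc / n_keep,
      _["var_genetic"] = s2g_acc / n_keep, _["var_residual"] = s2e_acc / n_keep,
      _["fitted"] = fit_acc / n_keep, _["n_samples"] = n_keep);
}
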