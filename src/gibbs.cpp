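// Single-site Gibbs samplers for the Bayesian alphabet whole-genome
// regression models (BRR, BL, Bayes A, Bayes B, Bayes Cpi) with standard
// conjugate full conditionals. Uses R's RNG so set.seed() makes chains
// reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// scaled-inverse-chi^2(df, scale): df*scale / chisq(df)
static double rinvchisq(double df, double scale_times_df) {
  return scale_times_df / R::rchisq(df);
}

// Inverse-Gaussian(mu, lambda), Michael-Schucany-Haas
static double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// model codes: 0 BRR, 1 BL, 2 BayesA, 3 BayesB, 4 BayesCpi
// [[Rcpp::export(name = ".gibbs_cpp")]]
List gibbs_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& Xd,
               int model, int n_iter, int burn_in, int thin,
               double df_a, double S_a, double df_e, double S_e,
               double pi0, double lambda_shape, double lambda_rate,
               bool fix_var_a, double sigma2_a_fixed,
               bool fix_var_e, double sigma2_e_fixed,
               bool store_effects) {
  const int n = y.n_elem, p = X.n_cols;
  const bool use_dom = Xd.n_cols > 0;
  const int pd = Xd.n_cols;

  arma::vec xtx(p), xdtxd(pd > 0 ? pd : 1);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));
  for (int j = 0; j < pd; ++j) xdtxd(j) = arma::dot(Xd.col(j), Xd.col(j));

  double vy = arma::var(y);
  double mu = arma::mean(y);
  arma::vec a(p, arma::fill::zeros), d(pd > 0 ? pd : 1, arma::fill::zeros);
  arma::vec e = y - mu;

  double sigma2_e = fix_var_e ? sigma2_e_fixed : 0.5 * vy;
  double sigma2_a = fix_var_a ? sigma2_a_fixed
                              : df_a * S_a / (df_a + 2.0); // prior mode
  arma::vec sigma2_aj(p); sigma2_aj.fill(sigma2_a);
  double sigma2_d = sigma2_a;
  arma::uvec delta(p, arma::fill::ones);
  double pi = (model == 3 || model == 4) ? pi0 : 0.0;
  if (model == 3 || model == 4) {
    // start with the prior fraction of markers in the model
    for (int j = 0; j < p; ++j) delta(j) = (R::unif_rand() < pi) ? 0 : 1;
  }
  arma::vec tau2(p, arma::fill::ones);
  double lambda2 = lambda_shape / std::max(lambda_rate, 1e-12);
  if (model == 1) lambda2 = 2.0 * p; // mild initial shrinkage for BL

  const int n_keep = (n_iter - burn_in) / thin;
  arma::vec a_sum(p, arma::fill::zeros), d_sum(pd > 0 ? pd : 1, arma::fill::zeros);
  arma::vec delta_sum(p, arma::fill::zeros);
  double mu_sum = 0, s2e_sum = 0, s2a_sum = 0, s2d_sum = 0, pi_sum = 0;
  arma::vec mu_chain(n_keep), s2e_chain(n_keep), s2a_chain(n_keep),
    pi_chain(n_keep);
  arma::mat a_chain;
  if (store_effects) a_chain.set_size(n_keep, p);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept
    e += mu;
    double ebar = arma::mean(e);
    mu = R::rnorm(ebar, std::sqrt(sigma2_e / n));
    e -= mu;

    // marker effects
    double ss_a = 0, ss_a_in = 0; int m_in = 0;
    for (int j = 0; j < p; ++j) {
      double aj_old = a(j);
      if (aj_old != 0.0) e += X.col(j) * aj_old;
      double xe = arma::dot(X.col(j), e);
      double vj; // prior variance of a_j for this model
      switch (model) {
        case 0: vj = sigma2_a; break;
        case 1: vj = tau2(j) * sigma2_e; break;
        default: vj = (model == 4) ? sigma2_a : sigma2_aj(j); break;
      }
      double aj = 0.0;
      if (model == 3 || model == 4) {
        // integrate a_j out to sample the inclusion indicator
        double v1 = xtx(j) * vj + sigma2_e;
        double log_ratio = 0.5 * std::log(sigma2_e / v1) +
          0.5 * xe * xe * vj / (sigma2_e * v1);
        double log_odds = std::log(1.0 - pi) - std::log(pi) + log_ratio;
        double pr_in = 1.0 / (1.0 + std::exp(-log_odds));
        delta(j) = (R::unif_rand() < pr_in) ? 1 : 0;
        if (delta(j) == 1) {
          double C = xtx(j) + sigma2_e / vj;
          aj = R::rnorm(xe / C, std::sqrt(sigma2_e / C));
        }
      } else {
        double C = xtx(j) + sigma2_e / vj;
        aj = R::rnorm(xe / C, std::sqrt(sigma2_e / C));
      }
      a(j) = aj;
      if (aj != 0.0) e -= X.col(j) * aj;
      ss_a += aj * aj;
      if (delta(j) == 1) { ss_a_in += aj * aj; ++m_in; }

      // marker-variance updates
      if (model == 2) {
        sigma2_aj(j) = rinvchisq(df_a + 1.0, aj * aj + df_a * S_a);
      } else if (model == 3) {
        sigma2_aj(j) = rinvchisq(df_a + delta(j), aj * aj + df_a * S_a);
      } else if (model == 1) {
        double aj2 = std::max(aj * aj, 1e-12);
        double minv = std::sqrt(lambda2 * sigma2_e / aj2);
        double ti = rinvgauss(minv, lambda2);
        tau2(j) = 1.0 / std::max(ti, 1e-12);
      }
    }

    // common variances
    if (model == 0 && !fix_var_a)
      sigma2_a = rinvchisq(df_a + p, ss_a + df_a * S_a);
    if (model == 4)
      sigma2_a = rinvchisq(df_a + m_in, ss_a_in + df_a * S_a);
    if (model == 4)
      pi = R::rbeta(p - m_in + 1.0, m_in + 1.0);
    if (model == 1)
      lambda2 = R::rgamma(lambda_shape + p,
                          1.0 / (lambda_rate + arma::accu(tau2) / 2.0));

    // dominance effects (ridge-style, own common variance)
    double ss_d = 0;
    if (use_dom) {
      for (int j = 0; j < pd; ++j) {
        if (d(j) != 0.0) e += Xd.col(j) * d(j);
        double xe = arma::dot(Xd.col(j), e);
        double C = xdtxd(j) + sigma2_e / sigma2_d;
        double dj = R::rnorm(xe / C, std::sqrt(sigma2_e / C));
        d(j) = dj;
        e -= Xd.col(j) * dj;
        ss_d += dj * dj;
      }
      sigma2_d = rinvchisq(df_a + pd, ss_d + df_a * S_a);
    }

    // residual variance
    if (!fix_var_e) {
      if (model == 1) {
        double q = 0;
        for (int j = 0; j < p; ++j) q += a(j) * a(j) / tau2(j);
        sigma2_e = rinvchisq(df_e + n + p, arma::dot(e, e) + q + df_e * S_e);
      } else {
        sigma2_e = rinvchisq(df_e + n, arma::dot(e, e) + df_e * S_e);
      }
    }

    if (!std::isfinite(mu) || !std::isfinite(sigma2_e) || !e.is_finite())
      stop("divergent chain: non-finite state at iteration %d", it);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      a_sum += a; delta_sum += arma::conv_to<arma::vec>::from(delta);
      if (use_dom) d_sum += d;
      mu_sum += mu; s2e_sum += sigma2_e; pi_sum += pi;
      s2a_sum += (model == 2 || model == 3) ? arma::mean(sigma2_aj) : sigma2_a;
      s2d_sum += sigma2_d;
      mu_chain(kept) = mu; s2e_chain(kept) = sigma2_e;
      s2a_chain(kept) = (model == 2 || model == 3) ? arma::mean(sigma2_aj)
                                                   : sigma2_a;
      pi_chain(kept) = pi;
      if (store_effects) a_chain.row(kept) = a.t();
      ++kept;
    }
  }

  List out = List::create(
    Named("mu") = mu_sum / kept,
    Named("add_effects") = a_sum / kept,
    Named("dom_effects") = use_dom ? NumericVector(wrap(d_sum / kept))
                                   : NumericVector(0),
    Named("marker_var") = s2a_sum / kept,
    Named("dom_var") = use_dom ? s2d_sum / kept : NA_REAL,
    Named("resid_var") = s2e_sum / kept,
    Named("pi") = (model == 4) ? pi_sum / kept : NA_REAL,
    Named("inclusion_prob") = delta_sum / kept,
    Named("n_samples_kept") = kept,
    Named("mu_chain") = mu_chain,
    Named("resid_var_chain") = s2e_chain,
    Named("marker_var_chain") = s2a_chain,
    Named("pi_chain") = pi_chain);
  if (store_effects) out["effect_samples"] = a_chain;
  return out;
}
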