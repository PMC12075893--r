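#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the EXNEX mixture model with a
// binomial likelihood on the logit scale:
//
//   y[k] ~ Binomial(n[k], inv_logit(theta[k]))
//   theta[k] = delta[k] * M1[k] + (1 - delta[k]) * M2[k]
//   M1[k] ~ N(mu, sigma^2)            (EX, shared hierarchical component)
//   M2[k] ~ N(nex_mean[k], nex_sd[k]^2)  (NEX, basket-specific prior)
//   delta[k] ~ Bernoulli(pi[k])
//   mu ~ N(mu_mean, mu_sd^2), sigma ~ half-normal(0, sigma_scale)
//
// delta and mu have conjugate full conditionals and are drawn exactly;
// theta[k] uses an independence Metropolis step proposing from a Laplace
// approximation of its log-concave conditional posterior; log(sigma)
// uses a random-walk step whose scale adapts during warmup only. The
// independent (NEX-only) analysis model is the special case pi = 0 with
// nex_* set to the independent prior.
//
// Uses R's RNG throughout so set.seed() in R gives bit-identical draws.

static inline double loglik_binom(double theta, double y, double n) {
  // binomial log-likelihood in theta up to the constant choose(n, y)
  return y * theta - n * Rf_log1pexp(theta);
}

// [[Rcpp::export(name = ".exnex_mcmc_cpp")]]
List exnex_mcmc_cpp(NumericVector y, NumericVector n,
                    NumericVector pi_ex,
                    NumericVector nex_mean, NumericVector nex_sd,
                    double mu_mean, double mu_sd, double sigma_scale,
                    int n_chains, int n_warmup, int n_samples, int thin,
                    bool hierarchical) {
  const int K = y.size();
  const int kept_per_chain = n_samples;
  const int total_kept = n_chains * kept_per_chain;

  NumericMatrix theta_draws(total_kept, K);
  IntegerMatrix delta_draws(total_kept, K);
  NumericVector mu_draws(total_kept);
  NumericVector sigma_draws(total_kept);
  NumericVector acc_theta(K);
  double acc_sigma = 0.0;

  RNGScope scope;

  int row = 0;
  for (int chain = 0; chain < n_chains; ++chain) {
    // initial values: empirical logits, jittered per chain
    std::vector<double> theta(K);
    std::vector<int> delta(K);
    for (int k = 0; k < K; ++k) {
      double ph = (y[k] + 0.5) / (n[k] + 1.0);
      theta[k] = std::log(ph / (1.0 - ph)) + 0.3 * norm_rand();
      delta[k] = (pi_ex[k] > 0.0 && unif_rand() < pi_ex[k]) ? 1 : 0;
    }
    double mu = mu_mean + 0.1 * norm_rand();
    double sigma = 0.5 * std::exp(0.3 * norm_rand());
    double step_eta = 0.5;

    const int n_iter = n_warmup + n_samples * thin;
    for (int iter = 0; iter < n_iter; ++iter) {
      const bool warm = iter < n_warmup;
      const double adapt = warm ? 1.0 / std::sqrt(1.0 + iter) : 0.0;

      if (hierarchical) {
        // delta[k] | theta[k], mu, sigma  (exact Bernoulli full conditional)
        for (int k = 0; k < K; ++k) {
          if (pi_ex[k] <= 0.0) { delta[k] = 0; continue; }
          if (pi_ex[k] >= 1.0) { delta[k] = 1; continue; }
          double l1 = std::log(pi_ex[k]) +
            Rf_dnorm4(theta[k], mu, sigma, 1);
          double l0 = std::log(1.0 - pi_ex[k]) +
            Rf_dnorm4(theta[k], nex_mean[k], nex_sd[k], 1);
          double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
          delta[k] = (unif_rand() < p1) ? 1 : 0;
        }
      }

      // theta[k] | rest: independence MH with a Laplace (normal)
      // approximation of the log-concave conditional posterior as the
      // proposal; near-iid draws, acceptance typically > 0.9
      for (int k = 0; k < K; ++k) {
        double pm, ps;
        if (hierarchical && delta[k] == 1) { pm = mu; ps = sigma; }
        else { pm = nex_mean[k]; ps = nex_sd[k]; }
        const double prec_prior = 1.0 / (ps * ps);
        // Newton iterations for the conditional mode, damped steps
        double m0 = std::log((y[k] + 0.5) / (n[k] - y[k] + 0.5));
        for (int it = 0; it < 6; ++it) {
          double pk = 1.0 / (1.0 + std::exp(-m0));
          double grad = y[k] - n[k] * pk - (m0 - pm) * prec_prior;
          double hess = n[k] * pk * (1.0 - pk) + prec_prior;
          double step = grad / hess;
          if (step > 4.0) step = 4.0; else if (step < -4.0) step = -4.0;
          m0 += step;
        }
        double pk = 1.0 / (1.0 + std::exp(-m0));
        // proposal sd inflated so the proposal dominates the target tails
        double s0 = 1.3 / std::sqrt(n[k] * pk * (1.0 - pk) + prec_prior);
        double prop = m0 + s0 * norm_rand();
        double logr =
          loglik_binom(prop, y[k], n[k]) -
            loglik_binom(theta[k], y[k], n[k]) +
          Rf_dnorm4(prop, pm, ps, 1) - Rf_dnorm4(theta[k], pm, ps, 1) +
          Rf_dnorm4(theta[k], m0, s0, 1) - Rf_dnorm4(prop, m0, s0, 1);
        bool acc = std::log(unif_rand()) < logr;
        if (acc) theta[k] = prop;
        if (!warm) acc_theta[k] += acc ? 1.0 : 0.0;
      }

      if (hierarchical) {
        // mu | theta_EX, sigma  (conjugate normal)
        double sum_ex = 0.0; int J = 0;
        for (int k = 0; k < K; ++k)
          if (delta[k] == 1) { sum_ex += theta[k]; ++J; }
        double prec = 1.0 / (mu_sd * mu_sd) + J / (sigma * sigma);
        double mean = (mu_mean / (mu_sd * mu_sd) + sum_ex / (sigma * sigma)) / prec;
        mu = mean + norm_rand() / std::sqrt(prec);

        // log(sigma) | theta_EX, mu  (MH; half-normal prior + Jacobian)
        double eta = std::log(sigma);
        double eta_prop = eta + step_eta * norm_rand();
        double sig_prop = std::exp(eta_prop);
        double logr = (eta_prop - sig_prop * sig_prop /
                         (2.0 * sigma_scale * sigma_scale)) -
                      (eta - sigma * sigma /
                         (2.0 * sigma_scale * sigma_scale));
        for (int k = 0; k < K; ++k)
          if (delta[k] == 1)
            logr += Rf_dnorm4(theta[k], mu, sig_prop, 1) -
                    Rf_dnorm4(theta[k], mu, sigma, 1);
        bool acc = std::log(unif_rand()) < logr;
        if (acc) sigma = sig_prop;
        if (warm) step_eta *= std::exp(adapt * ((acc ? 1.0 : 0.0) - 0.44));
        else acc_sigma += acc ? 1.0 : 0.0;
      }

      if (!warm) {
        int since = iter - n_warmup;
        if (since % thin == 0) {
          for (int k = 0; k < K; ++k) {
            theta_draws(row, k) = theta[k];
            delta_draws(row, k) = delta[k];
          }
          mu_draws[row] = mu;
          sigma_draws[row] = sigma;
          ++row;
        }
      }
    }
  }

  double denom = (double)n_chains * n_samples * thin;
  for (int k = 0; k < K; ++k) acc_theta[k] /= denom;

  return List::create(
    _["theta"] = theta_draws,
    _["delta"] = delta_draws,
    _["mu"] = mu_draws,
    _["sigma"] = sigma_draws,
    _["accept_theta"] = acc_theta,
    _["accept_sigma"] = acc_sigma / denom);
}
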