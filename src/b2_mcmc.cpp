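#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// numerically safe log(1 + exp(x))
static inline double softplus(double x) {
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  if (x > -37.0) return std::log1p(std::exp(x));
  return std::exp(x);
}

// Bernoulli-logit log-likelihood increment for one dyad
static inline double dyad_ll(int y, double eta) {
  return y * eta - softplus(eta);
}

// Metropolis-within-Gibbs sampler for the undirected dyadic
// random-effects logistic (b2) model:
//   y_ij ~ Bernoulli(logit^-1(mu + sum_k gamma_k z_ijk + A_i + A_j)),
//   A_i ~ N(0, sigma2), over eligible dyads only.
// Random-walk proposals for mu, each gamma_k and each A_i; conjugate
// inverse-gamma draw for sigma2 given A. Proposal scales adapt during
// burn-in toward ~35% acceptance and are frozen afterwards. Actor
// effects are re-centred each sweep with the mean absorbed into mu
// (eta is unchanged by this move). Uses R's RNG, so draws are
// reproducible under set.seed().
// sigma_fixed < 0  : sigma2 is sampled (inverse-gamma prior)
// sigma_fixed == 0 : actor effects pinned at zero (plain dyadic logistic)
// sigma_fixed > 0  : actor effects sampled with sigma held fixed
// [[Rcpp::export]]
List b2_mcmc_chain(const IntegerVector& dyad_i,
                   const IntegerVector& dyad_j,
                   const IntegerVector& y,
                   const NumericMatrix& Z,
                   int n_actors,
                   int n_burnin, int n_iter, int thin,
                   double prior_sd_fixed, double prior_a, double prior_b,
                   double sigma_fixed,
                   bool store_actor) {
  const int D = dyad_i.size();
  const int K = Z.ncol();
  const int n_keep = n_iter / thin;
  const double prior_prec = 1.0 / (prior_sd_fixed * prior_sd_fixed);

  std::vector<std::vector<int> > actor_dyads(n_actors);
  for (int d = 0; d < D; ++d) {
    actor_dyads[dyad_i[d]].push_back(d);
    actor_dyads[dyad_j[d]].push_back(d);
  }

  // initial state
  double edges = 0.0;
  for (int d = 0; d < D; ++d) edges += y[d];
  double p0 = (edges + 1.0) / (D + 2.0);
  double mu = std::log(p0 / (1.0 - p0));
  std::vector<double> gamma(K, 0.0), A(n_actors, 0.0);
  bool sample_sigma = sigma_fixed < 0.0;
  bool sample_A = sigma_fixed != 0.0;
  double sigma2 = sample_sigma ? 0.25 : sigma_fixed * sigma_fixed;

  std::vector<double> eta(D);
  for (int d = 0; d < D; ++d) {
    double e = mu;
    for (int k = 0; k < K; ++k) e += gamma[k] * Z(d, k);
    eta[d] = e;  // A is zero
  }

  // adaptive proposal scales
  double s_mu = 0.2;
  std::vector<double> s_gamma(K, 0.2), s_A(n_actors, 0.5);
  int acc_mu = 0, try_mu = 0;
  std::vector<int> acc_gamma(K, 0), try_gamma(K, 0);
  std::vector<int> acc_A(n_actors, 0), try_A(n_actors, 0);
  long long acc_mu_tot = 0, acc_gamma_tot = 0, acc_A_tot = 0;
  long long try_mu_tot = 0, try_gamma_tot = 0, try_A_tot = 0;
  const int adapt_every = 50;
  const double target = 0.35;

  NumericVector draw_mu(n_keep), draw_sigma(n_keep);
  NumericMatrix draw_gamma(n_keep, K);
  NumericMatrix draw_A(store_actor ? n_keep : 0,
                       store_actor ? n_actors : 0);

  RNGScope scope;
  int keep = 0;
  for (int it = 0; it < n_burnin + n_iter; ++it) {
    bool burn = it < n_burnin;

    // mu: global shift of eta
    {
      double delta = norm_rand() * s_mu;
      double dll = 0.0;
      for (int d = 0; d < D; ++d)
        dll += dyad_ll(y[d], eta[d] + delta) - dyad_ll(y[d], eta[d]);
      double mu_new = mu + delta;
      dll += -0.5 * prior_prec * (mu_new * mu_new - mu * mu);
      ++try_mu;
      if (std::log(unif_rand()) < dll) {
        mu = mu_new;
        for (int d = 0; d < D; ++d) eta[d] += delta;
        ++acc_mu;
      }
    }

    // each gamma_k: shift of eta by delta * Z[,k]
    for (int k = 0; k < K; ++k) {
      double delta = norm_rand() * s_gamma[k];
      double dll = 0.0;
      for (int d = 0; d < D; ++d) {
        double z = Z(d, k);
        if (z != 0.0)
          dll += dyad_ll(y[d], eta[d] + delta * z) - dyad_ll(y[d], eta[d]);
      }
      double g_new = gamma[k] + delta;
      dll += -0.5 * prior_prec * (g_new * g_new - gamma[k] * gamma[k]);
      ++try_gamma[k];
      if (std::log(unif_rand()) < dll) {
        gamma[k] = g_new;
        for (int d = 0; d < D; ++d) eta[d] += delta * Z(d, k);
        ++acc_gamma[k];
      }
    }

    if (sample_A) {
      // each actor effect: shift of eta on incident dyads
      for (int i = 0; i < n_actors; ++i) {
        double delta = norm_rand() * s_A[i];
        double dll = 0.0;
        const std::vector<int>& dd = actor_dyads[i];
        for (size_t m = 0; m < dd.size(); ++m) {
          int d = dd[m];
          dll += dyad_ll(y[d], eta[d] + delta) - dyad_ll(y[d], eta[d]);
        }
        double a_new = A[i] + delta;
        dll += -0.5 * (a_new * a_new - A[i] * A[i]) / sigma2;
        ++try_A[i];
        if (std::log(unif_rand()) < dll) {
          A[i] = a_new;
          for (size_t m = 0; m < dd.size(); ++m) eta[dd[m]] += delta;
          ++acc_A[i];
        }
      }

      if (sample_sigma) {
        // conjugate inverse-gamma draw for sigma2 | A
        double ssq = 0.0;
        for (int i = 0; i < n_actors; ++i) ssq += A[i] * A[i];
        double shape = prior_a + 0.5 * n_actors;
        double rate = prior_b + 0.5 * ssq;
        sigma2 = rate / R::rgamma(shape, 1.0);
      }

      // re-centre actor effects; eta is invariant under this move
      double mean_A = 0.0;
      for (int i = 0; i < n_actors; ++i) mean_A += A[i];
      mean_A /= n_actors;
      for (int i = 0; i < n_actors; ++i) A[i] -= mean_A;
      mu += 2.0 * mean_A;
    }

    if (burn && ((it + 1) % adapt_every == 0)) {
      s_mu *= std::exp(2.0 * ((double)acc_mu / try_mu - target));
      s_mu = std::min(std::max(s_mu, 1e-3), 10.0);
      acc_mu = 0; try_mu = 0;
      for (int k = 0; k < K; ++k) {
        s_gamma[k] *= std::exp(2.0 * ((double)acc_gamma[k] / try_gamma[k]
                                      - target));
        s_gamma[k] = std::min(std::max(s_gamma[k], 1e-3), 10.0);
        acc_gamma[k] = 0; try_gamma[k] = 0;
      }
      if (sample_A) {
        for (int i = 0; i < n_actors; ++i) {
          if (try_A[i] == 0) continue;
          s_A[i] *= std::exp(2.0 * ((double)acc_A[i] / try_A[i] - target));
          s_A[i] = std::min(std::max(s_A[i], 1e-3), 10.0);
          acc_A[i] = 0; try_A[i] = 0;
        }
      }
    }
    if (!burn) {
      acc_mu_tot += acc_mu; try_mu_tot += try_mu;
      // running totals reuse the adaptation counters post-burn-in; reset
      // so they are not double-counted
      acc_mu = 0; try_mu = 0;
      for (int k = 0; k < K; ++k) {
        acc_gamma_tot += acc_gamma[k]; try_gamma_tot += try_gamma[k];
        acc_gamma[k] = 0; try_gamma[k] = 0;
      }
      for (int i = 0; i < n_actors; ++i) {
        acc_A_tot += acc_A[i]; try_A_tot += try_A[i];
        acc_A[i] = 0; try_A[i] = 0;
      }
    }

    if (!burn && ((it - n_burnin + 1) % thin == 0)) {
      draw_mu[keep] = mu;
      for (int k = 0; k < K; ++k) draw_gamma(keep, k) = gamma[k];
      draw_sigma[keep] = std::sqrt(sigma2);
      if (store_actor)
        for (int i = 0; i < n_actors; ++i) draw_A(keep, i) = A[i];
      ++keep;
    }

    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  double acc_rate_mu = try_mu_tot ? (double)acc_mu_tot / try_mu_tot : NA_REAL;
  double acc_rate_gamma = try_gamma_tot ?
    (double)acc_gamma_tot / try_gamma_tot : NA_REAL;
  double acc_rate_A = try_A_tot ? (double)acc_A_tot / try_A_tot : NA_REAL;

  return List::create(_["mu"] = draw_mu,
                      _["gamma"] = draw_gamma,
                      _["sigma_a"] = draw_sigma,
                      _["actor_effects"] = draw_A,
                      _["accept"] = NumericVector::create(
                        _["mu"] = acc_rate_mu,
                        _["gamma"] = acc_rate_gamma,
                        _["actor"] = acc_rate_A));
}
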