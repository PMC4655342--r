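#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli log likelihood of per-level counts under the 4-parameter
// logistic psychometric function. Returns -inf (never NaN) when a
// saturated psi collides with discordant counts.
static double loglik(const NumericVector &p, const NumericVector &k,
                     const NumericVector &n, double m, double w,
                     double fl, double ce) {
  double ll = 0.0;
  for (int i = 0; i < p.size(); ++i) {
    double z = (p[i] - m) / w;
    double s = 1.0 / (1.0 + std::exp(-z));
    double ps = fl + (ce - fl) * s;
    if (k[i] > 0.0) {
      if (ps <= 0.0) return R_NegInf;
      ll += k[i] * std::log(ps);
    }
    double r = n[i] - k[i];
    if (r > 0.0) {
      if (ps >= 1.0) return R_NegInf;
      ll += r * std::log1p(-ps);
    }
  }
  if (std::isnan(ll)) return R_NegInf;
  return ll;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Log target on the unconstrained scale: likelihood at theta(z) plus the
// log-Jacobian of the scaled-logit transform (uniform prior densities are
// constant over the box and added back in R).
static double log_target_z(const NumericVector &p, const NumericVector &k,
                           const NumericVector &n, const double z[4],
                           const NumericMatrix &bounds, double theta[4]) {
  double ljac = 0.0;
  for (int j = 0; j < 4; ++j) {
    double s = sigmoid(z[j]);
    double lo = bounds(j, 0), hi = bounds(j, 1);
    theta[j] = lo + (hi - lo) * s;
    // d theta / d z = (hi - lo) s (1 - s); log via softplus for stability
    double sp = (z[j] > 0) ? z[j] + std::log1p(std::exp(-z[j]))
                           : std::log1p(std::exp(z[j]));
    ljac += std::log(hi - lo) + z[j] - 2.0 * sp;
  }
  double ll = loglik(p, k, n, theta[0], theta[1], theta[2], theta[3]);
  if (!std::isfinite(ll)) return R_NegInf;
  return ll + ljac;
}

// One chain of component-wise Gaussian random-walk Metropolis with
// Robbins-Monro scale adaptation during warmup only. Uses R's RNG so a
// set.seed() call in R makes the chain reproducible.
// [[Rcpp::export]]
List rwm_chain(NumericVector p, NumericVector k, NumericVector n,
               NumericMatrix bounds, NumericVector z_init,
               int n_warmup, int n_draws, int thin, double target_accept,
               NumericVector log_scale_init) {
  RNGScope scope;
  double z[4], theta[4];
  for (int j = 0; j < 4; ++j) z[j] = z_init[j];
  double ls[4];
  for (int j = 0; j < 4; ++j) ls[j] = log_scale_init[j];

  double lp = log_target_z(p, k, n, z, bounds, theta);
  if (!std::isfinite(lp)) stop("Initial log posterior is not finite.");

  int total = n_warmup + n_draws * thin;
  NumericMatrix draws(n_draws, 4);
  NumericVector ll_out(n_draws);
  IntegerVector acc_count(4);
  NumericVector scales_postwarmup(4), scales_final(4);
  int stored = 0;

  for (int t = 1; t <= total; ++t) {
    bool warm = t <= n_warmup;
    for (int j = 0; j < 4; ++j) {
      double zprop[4] = {z[0], z[1], z[2], z[3]};
      zprop[j] += std::exp(ls[j]) * R::norm_rand();
      double thprop[4];
      double lpprop = log_target_z(p, k, n, zprop, bounds, thprop);
      double a = std::exp(std::min(0.0, lpprop - lp));
      bool accept = std::isfinite(lpprop) && (R::unif_rand() < a);
      if (accept) {
        z[j] = zprop[j];
        lp = lpprop;
        for (int q = 0; q < 4; ++q) theta[q] = thprop[q];
        if (!warm) acc_count[j]++;
      }
      if (warm) {
        double rate = std::isfinite(lpprop) ? a : 0.0;
        ls[j] += std::pow((double)t, -0.6) * (rate - target_accept);
      }
    }
    if (t == n_warmup) {
      for (int j = 0; j < 4; ++j) scales_postwarmup[j] = std::exp(ls[j]);
    }
    if (!warm && ((t - n_warmup) % thin == 0)) {
      for (int j = 0; j < 4; ++j) draws(stored, j) = theta[j];
      ll_out[stored] = loglik(p, k, n, theta[0], theta[1], theta[2], theta[3]);
      ++stored;
    }
  }
  for (int j = 0; j < 4; ++j) scales_final[j] = std::exp(ls[j]);

  return List::create(
    _["draws"] = draws, _["loglik"] = ll_out,
    _["accept_rate"] = NumericVector(acc_count) / (double)(n_draws * thin),
    _["scales_postwarmup"] = scales_postwarmup,
    _["scales_final"] = scales_final);
}
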