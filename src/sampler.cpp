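#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Prior family codes: 0 = beta(p1, p2), 1 = gamma(shape p1, rate p2),
// 2 = uniform(p1, p2). Parameter order: m, v, c, l, sigma_proc, sigma_nobs.

static double prior_logdens(double x, int fam, double p1, double p2) {
  switch (fam) {
  case 0: return R::dbeta(x, p1, p2, 1);
  case 1: return R::dgamma(x, p1, 1.0 / p2, 1); // R::dgamma takes scale
  case 2: return R::dunif(x, p1, p2, 1);
  }
  return R_NegInf;
}

// Joint log posterior: priors + initial state + lognormal process +
// negative-binomial (gamma-Poisson marginal) observation terms.
static double log_post(const std::vector<double>& par,
                       const std::vector<double>& lat,
                       const IntegerVector& nobs,
                       const NumericVector& repro,
                       const IntegerVector& fam,
                       const NumericVector& p1,
                       const NumericVector& p2) {
  const double m = par[0], v = par[1], c = par[2], l = par[3];
  const double sp = par[4], sn = par[5];
  // each rate lives in [0,1]; the sum may exceed 1 as long as every
  // process median stays positive (recruitment can offset survival), which
  // keeps the joint prior the product of the independent priors
  if (!(m >= 0.0 && m <= 1.0 && v >= 0.0 && v <= 1.0 && c >= 0.0 && c <= 1.0))
    return R_NegInf;
  if (l < 0.0 || sp <= 0.0 || sn < 0.0) return R_NegInf;

  double lp = 0.0;
  for (int j = 0; j < 6; j++) lp += prior_logdens(par[j], fam[j], p1[j], p2[j]);
  if (!R_finite(lp)) return R_NegInf;

  const int T = nobs.size();
  if (T == 0) return lp;
  for (int t = 0; t < T; t++)
    if (!(lat[t] > 0.0) || !R_finite(lat[t])) return R_NegInf;

  // weakly informative initial state: lognormal centred on first count
  double centre = nobs[0] > 1 ? (double)nobs[0] : 1.0;
  lp += R::dlnorm(lat[0], std::log(centre), 0.5, 1);

  const double surv = 1.0 - m - v - c;
  for (int t = 1; t < T; t++) {
    double mu = surv * lat[t - 1] + l * repro[t];
    if (!(mu > 0.0)) return R_NegInf;
    lp += R::dlnorm(lat[t], std::log(mu), sp, 1);
  }
  for (int t = 0; t < T; t++) {
    if (sn == 0.0) {
      lp += R::dpois(nobs[t], lat[t], 1);
    } else {
      double size = lat[t] * lat[t] / (sn * sn);
      lp += R::dnbinom_mu(nobs[t], size, lat[t], 1);
    }
  }
  return R_finite(lp) ? lp : R_NegInf;
}

// [[Rcpp::export(name = ".lp_cpp")]]
double lp_cpp(NumericVector params, NumericVector latent,
              IntegerVector nobs, NumericVector repro,
              IntegerVector fam, NumericVector p1, NumericVector p2) {
  std::vector<double> par(params.begin(), params.end());
  std::vector<double> lat(latent.begin(), latent.end());
  return log_post(par, lat, nobs, repro, fam, p1, p2);
}

// Block transforms: logit on (0,1) for m, v, c; log for everything else.
// Proposals walk on the transformed scale, so the Jacobian of the changed
// block enters the Metropolis ratio.
static inline bool is_logit_block(int j) { return j < 3; }

static inline double log_jac(int j, double theta) {
  if (is_logit_block(j)) return std::log(theta) + std::log1p(-theta);
  return std::log(theta);
}

static inline double to_z(int j, double theta) {
  if (is_logit_block(j)) return std::log(theta / (1.0 - theta));
  return std::log(theta);
}

static inline double from_z(int j, double z) {
  if (is_logit_block(j)) return 1.0 / (1.0 + std::exp(-z));
  return std::exp(z);
}

// Adaptive random-walk Metropolis-within-Gibbs. One block per model
// parameter and per latent state; step sizes adapt toward 44% acceptance
// during burn-in only (Robbins-Monro on the log step), then freeze.
// [[Rcpp::export(name = ".mwg_chain")]]
List mwg_chain(IntegerVector nobs, NumericVector repro,
               IntegerVector fam, NumericVector p1, NumericVector p2,
               NumericVector init_params, NumericVector init_latent,
               int n_burn, int n_keep, int thin, double target_accept) {
  const int T = nobs.size();
  const int nb = 6 + T;
  std::vector<double> par(init_params.begin(), init_params.end());
  std::vector<double> lat(init_latent.begin(), init_latent.end());

  double cur_lp = log_post(par, lat, nobs, repro, fam, p1, p2);
  if (!R_finite(cur_lp)) stop("log posterior not finite at the initial state");

  std::vector<double> lstep(nb, std::log(0.3));
  std::vector<long> acc_post(nb, 0), try_post(nb, 0);
  // windowed adaptation: each block's step adjusts from the acceptance
  // rate of the last window, with a damped but floored scale so steps keep
  // tracking the posterior geometry until the end of burn-in
  const int win = 100;
  std::vector<int> acc_win(nb, 0);
  NumericMatrix draws(n_keep, nb);

  const long total = (long)n_burn + (long)n_keep * thin;
  int kept = 0;
  for (long it = 0; it < total; it++) {
    const bool adapting = it < n_burn;
    for (int j = 0; j < nb; j++) {
      double theta = j < 6 ? par[j] : lat[j - 6];
      // transform index: latent blocks use the log scale too
      int tr = j < 6 ? j : 6;
      double z = to_z(tr < 6 ? tr : 6, theta);
      double zprop = z + std::exp(lstep[j]) * norm_rand();
      double thprop = from_z(tr < 6 ? tr : 6, zprop);

      double old_val = theta;
      double lp_new;
      if (j < 6) {
        par[j] = thprop;
        lp_new = log_post(par, lat, nobs, repro, fam, p1, p2);
      } else {
        lat[j - 6] = thprop;
        lp_new = log_post(par, lat, nobs, repro, fam, p1, p2);
      }
      double lr = (lp_new + log_jac(tr < 6 ? tr : 6, thprop)) -
                  (cur_lp + log_jac(tr < 6 ? tr : 6, old_val));
      bool accept = R_finite(lp_new) && std::log(unif_rand()) < lr;
      if (accept) {
        cur_lp = lp_new;
      } else {
        if (j < 6) par[j] = old_val; else lat[j - 6] = old_val;
      }
      if (adapting) {
        if (accept) acc_win[j]++;
        if ((it + 1) % win == 0) {
          double rate = (double)acc_win[j] / win;
          long w = (it + 1) / win;
          double scale = std::max(0.1, 1.5 / std::sqrt((double)w));
          lstep[j] += scale * (rate - target_accept);
          acc_win[j] = 0;
        }
      } else {
        try_post[j]++;
        if (accept) acc_post[j]++;
      }
    }
    if (!adapting && ((it - n_burn + 1) % thin == 0)) {
      for (int j = 0; j < 6; j++) draws(kept, j) = par[j];
      for (int t = 0; t < T; t++) draws(kept, 6 + t) = lat[t];
      kept++;
    }
  }

  NumericVector acc(nb), steps(nb);
  for (int j = 0; j < nb; j++) {
    acc[j] = try_post[j] > 0 ? (double)acc_post[j] / try_post[j] : NA_REAL;
    steps[j] = std::exp(lstep[j]);
  }
  return List::create(_["draws"] = draws, _["accept"] = acc,
                      _["step"] = steps, _["final_lp"] = cur_lp);
}
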