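#include <Rcpp.h>
using namespace Rcpp;

// Component-wise Gibbs samplers for the contrast-based normal NMA model.
// Node 0 is the reference with d[0] fixed at 0; a and b are 0-based node
// indices so that y[i] ~ N(d[a[i]] - d[b[i]], 1/w[i]).
// R's RNG is used throughout, so set.seed() on the R side makes runs
// reproducible and per-chain seeds independent.

static inline void draw_d(std::vector<double>& d,
                          const IntegerVector& a, const IntegerVector& b,
                          const std::vector<double>& y, const double* w,
                          int n_nodes, double prior_prec) {
  const int m = a.size();
  for (int k = 1; k < n_nodes; ++k) {
    double prec = prior_prec, mw = 0.0;
    for (int i = 0; i < m; ++i) {
      if (a[i] == k)      { prec += w[i]; mw += w[i] * (y[i] + d[b[i]]); }
      else if (b[i] == k) { prec += w[i]; mw += w[i] * (d[a[i]] - y[i]); }
    }
    d[k] = mw / prec + norm_rand() / std::sqrt(prec);
  }
}

// [[Rcpp::export]]
NumericMatrix gibbs_fixed_cpp(IntegerVector a, IntegerVector b,
                              NumericVector y, NumericVector w,
                              int n_nodes, int n_samples, int burn_in,
                              int thin, double prior_prec) {
  const int m = y.size(), nfree = n_nodes - 1;
  const int keep = n_samples / thin;
  NumericMatrix out(keep, nfree);
  std::vector<double> d(n_nodes, 0.0), yv(y.begin(), y.end());
  int idx = 0;
  const int total = burn_in + n_samples;
  for (int it = 0; it < total; ++it) {
    draw_d(d, a, b, yv, REAL(w), n_nodes, prior_prec);
    if (it >= burn_in && ((it - burn_in) % thin) == thin - 1) {
      for (int k = 1; k < n_nodes; ++k) out(idx, k - 1) = d[k];
      ++idx;
    }
  }
  return out;
}

// [[Rcpp::export]]
List gibbs_random_cpp(IntegerVector a, IntegerVector b,
                      NumericVector y, NumericVector w,
                      int n_nodes, int n_samples, int burn_in, int thin,
                      double prior_prec, double tau_max, double tau_init) {
  const int m = y.size(), nfree = n_nodes - 1;
  const int keep = n_samples / thin;
  NumericMatrix out_d(keep, nfree), out_delta(keep, m);
  NumericVector out_tau(keep);
  std::vector<double> d(n_nodes, 0.0), delta(m, 0.0);
  double tau = tau_init > 0.0 && tau_init < tau_max ? tau_init : 0.5 * tau_max;
  int idx = 0;
  const int total = burn_in + n_samples;
  for (int it = 0; it < total; ++it) {
    const double tp = 1.0 / (tau * tau);
    // study-level effects: conjugate normal given d and tau
    for (int i = 0; i < m; ++i) {
      const double mu = d[a[i]] - d[b[i]];
      const double prec = w[i] + tp;
      delta[i] = (w[i] * y[i] + tp * mu) / prec +
                 norm_rand() / std::sqrt(prec);
    }
    // basic parameters given delta: same conditional as the fixed model
    // with delta as data and 1/tau^2 as the weight
    for (int k = 1; k < n_nodes; ++k) {
      double prec = prior_prec, mw = 0.0;
      for (int i = 0; i < m; ++i) {
        if (a[i] == k)      { prec += tp; mw += tp * (delta[i] + d[b[i]]); }
        else if (b[i] == k) { prec += tp; mw += tp * (d[a[i]] - delta[i]); }
      }
      d[k] = mw / prec + norm_rand() / std::sqrt(prec);
    }
    // tau: slice sample f(tau) = tau^-m exp(-S/(2 tau^2)) on (0, tau_max),
    // the conditional under a Uniform(0, tau_max) prior on tau
    double S = 0.0;
    for (int i = 0; i < m; ++i) {
      const double r = delta[i] - (d[a[i]] - d[b[i]]);
      S += r * r;
    }
    const double logf0 = -m * std::log(tau) - S / (2.0 * tau * tau);
    const double logu = logf0 - exp_rand();
    double lo = 0.0, hi = tau_max;
    for (int tries = 0; tries < 1000; ++tries) {
      const double cand = lo + unif_rand() * (hi - lo);
      const double lf = -m * std::log(cand) - S / (2.0 * cand * cand);
      if (lf >= logu) { tau = cand; break; }
      if (cand < tau) lo = cand; else hi = cand;
    }
    if (it >= burn_in && ((it - burn_in) % thin) == thin - 1) {
      for (int k = 1; k < n_nodes; ++k) out_d(idx, k - 1) = d[k];
      for (int i = 0; i < m; ++i) out_delta(idx, i) = delta[i];
      out_tau[idx] = tau;
      ++idx;
    }
  }
  return List::create(_["d"] = out_d, _["delta"] = out_delta,
                      _["tau"] = out_tau);
}
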