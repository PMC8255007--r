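#include <Rcpp.h>
using namespace Rcpp;

// Marginal log-likelihood of the right-hand side r = x'e* for one locus,
// with the locus effect integrated out: r ~ N(0, xx*ve + xx^2*s).
static inline double locus_loglik(double r, double xx, double ve, double s) {
  double v = xx * ve + xx * xx * s;
  return -0.5 * (std::log(v) + r * r / v);
}

// Draw from a scaled inverse chi-square(df, scale).
static inline double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// BayesB Gibbs chain with a per-locus Metropolis-Hastings step for the
// locus variance (prior: point mass at zero with probability pi, else
// scaled inverse chi-square(nu, s_beta)), effects sampled from their
// conditional normal, residual variance from its conditional.
// X: centered dosage matrix (animals x markers), y: response.
// Uses R's RNG, so set.seed() in the caller makes chains reproducible.
// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(NumericMatrix X, NumericVector y, double pi0,
                 int n_iter, int burnin, int thin,
                 double nu, double s_beta, int mh_cycles) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += X(i, j) * X(i, j);
    xx[j] = acc;
  }

  std::vector<double> beta(p, 0.0), svar(p, 0.0);
  double mu = Rcpp::mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double ve = 0.0;
  for (int i = 0; i < n; ++i) ve += e[i] * e[i];
  ve = ve / n * 0.5;
  if (ve <= 0) ve = 1e-8;

  int n_keep = (n_iter - burnin) / thin;
  NumericMatrix beta_samp(n_keep, p);
  NumericVector ve_samp(n_keep), mu_samp(n_keep);
  NumericVector incl_mean(p);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // overall mean (flat prior): mu | rest ~ N(mu + ebar, ve/n)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(ve / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0) continue;
      // remove locus j from the residual
      if (beta[j] != 0.0) {
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * beta[j];
      }
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];

      // MH on the locus variance with the effect integrated out;
      // proposal = prior mixture, so the ratio is the likelihood ratio
      double s_cur = svar[j];
      double ll_cur = locus_loglik(r, xx[j], ve, s_cur);
      for (int c = 0; c < mh_cycles; ++c) {
        double s_prop = (unif_rand() < pi0) ? 0.0 : rscinvchisq(nu, s_beta);
        double ll_prop = locus_loglik(r, xx[j], ve, s_prop);
        if (std::log(unif_rand()) < ll_prop - ll_cur) {
          s_cur = s_prop;
          ll_cur = ll_prop;
        }
      }
      svar[j] = s_cur;

      if (s_cur > 0.0) {
        double c_inv = 1.0 / (xx[j] + ve / s_cur);
        double bhat = r * c_inv;
        beta[j] = bhat + R::norm_rand() * std::sqrt(ve * c_inv);
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * beta[j];
      } else {
        beta[j] = 0.0;
      }
    }

    // residual variance (flat scaled prior)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    ve = sse / R::rchisq((double)n - 2.0);
    if (!std::isfinite(ve) || ve <= 0.0) {
      stop("divergent chain: residual variance non-finite at iteration %d",
           it + 1);
    }

    if (it >= burnin && ((it - burnin) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < p; ++j) {
        beta_samp(kept, j) = beta[j];
        if (beta[j] != 0.0) incl_mean[j] += 1.0;
      }
      ve_samp[kept] = ve;
      mu_samp[kept] = mu;
      ++kept;
    }
  }
  for (int j = 0; j < p; ++j) incl_mean[j] /= std::max(kept, 1);

  return List::create(
    _["beta"] = beta_samp, _["ve"] = ve_samp, _["mu"] = mu_samp,
    _["inclusion"] = incl_mean, _["n_kept"] = kept);
}
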