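#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sampler for the BayesC mixture model
//   y = W beta + X c + e,  c_k = 0 with prior prob pi,
//   c_k | delta_k=1 ~ N(0, sigma2_c) with a common effect variance.
// Fixed effects carry flat priors; variances carry scaled-inverse-chi-square
// priors with df nu and scale chosen upstream so the prior mean equals the
// configured variance. fix_var freezes both variances (df -> infinity),
// which with pi = 0 makes the posterior mean the ridge solution.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List bayesc_gibbs(NumericVector y, NumericMatrix W, NumericMatrix X,
                  double pi, int chain_length, int burn_in,
                  double sigma2_c0, double sigma2_e0,
                  double nu_c, double nu_e, bool fix_var, int thin) {
  const int n = y.size(), pw = W.ncol(), m = X.ncol();
  std::vector<double> beta(pw, 0.0), c(m, 0.0);
  std::vector<int> delta(m, 0);
  std::vector<double> e(y.begin(), y.end());
  std::vector<double> wtw(pw), xtx(m);
  for (int j = 0; j < pw; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    wtw[j] = s;
  }
  for (int k = 0; k < m; ++k) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xtx[k] = s;
  }
  double sigma2_c = sigma2_c0, sigma2_e = sigma2_e0;
  // scale so that the prior mean (nu S / (nu - 2)) equals the configured value
  const double Sc = (nu_c > 2) ? sigma2_c0 * (nu_c - 2.0) / nu_c : sigma2_c0;
  const double Se = (nu_e > 2) ? sigma2_e0 * (nu_e - 2.0) / nu_e : sigma2_e0;
  const double log_prior_odds =
      (pi > 0.0 && pi < 1.0) ? std::log((1.0 - pi) / pi) : 0.0;

  std::vector<double> mf(m, 0.0), ceff(m, 0.0), bmean(pw, 0.0);
  double acc_sc = 0, acc_se = 0, acc_gv = 0;
  std::vector<double> tr_sc, tr_se, tr_gv;
  int n_keep = 0;

  for (int it = 0; it < chain_length; ++it) {
    // (a) fixed effects from their conditional normals (flat prior)
    for (int j = 0; j < pw; ++j) {
      if (wtw[j] <= 0) continue;
      double r = 0; for (int i = 0; i < n; ++i) r += W(i, j) * e[i];
      double bhat = beta[j] + r / wtw[j];
      double bnew = R::rnorm(bhat, std::sqrt(sigma2_e / wtw[j]));
      double d = bnew - beta[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= W(i, j) * d;
      beta[j] = bnew;
    }
    // (b) markers: inclusion indicator (effect marginalized), then effect
    int m_in = 0; double ssc = 0;
    for (int k = 0; k < m; ++k) {
      if (xtx[k] <= 0) { delta[k] = 0; c[k] = 0; continue; }
      double r = 0; for (int i = 0; i < n; ++i) r += X(i, k) * e[i];
      if (delta[k]) r += xtx[k] * c[k];        // residual excluding marker k
      bool inc;
      if (pi <= 0.0) inc = true;
      else {
        double v0 = xtx[k] * sigma2_e;
        double v1 = xtx[k] * xtx[k] * sigma2_c + v0;
        double logBF = -0.5 * std::log(v1 / v0) +
                       0.5 * r * r * (1.0 / v0 - 1.0 / v1);
        double prob = 1.0 / (1.0 + std::exp(-(log_prior_odds + logBF)));
        inc = (R::unif_rand() < prob);
      }
      double cold = delta[k] ? c[k] : 0.0;
      double cnew = 0.0;
      if (inc) {
        double lambda = xtx[k] / sigma2_e + 1.0 / sigma2_c;
        cnew = R::rnorm((r / sigma2_e) / lambda, std::sqrt(1.0 / lambda));
        ++m_in;
        ssc += cnew * cnew;
      }
      double d = cnew - cold;
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= X(i, k) * d;
      c[k] = cnew;
      delta[k] = inc ? 1 : 0;
    }
    // (c) variances from scaled-inverse-chi-square conditionals
    if (!fix_var) {
      sigma2_c = (nu_c * Sc + ssc) / R::rchisq(nu_c + m_in);
      double sse = 0; for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = (nu_e * Se + sse) / R::rchisq(nu_e + n);
      if (!R_finite(sigma2_c) || !R_finite(sigma2_e) ||
          sigma2_c <= 0 || sigma2_e <= 0)
        stop("divergent variance sample at sweep %d "
             "(sigma2_c=%g, sigma2_e=%g)", it + 1, sigma2_c, sigma2_e);
    }
    if (it >= burn_in) {
      ++n_keep;
      for (int k = 0; k < m; ++k) {
        if (delta[k]) mf[k] += 1.0;
        ceff[k] += c[k];
      }
      for (int j = 0; j < pw; ++j) bmean[j] += beta[j];
      // realized genetic variance of this sample: var(y - W beta - e)
      double s1 = 0, s2 = 0;
      for (int i = 0; i < n; ++i) {
        double wi = 0;
        for (int j = 0; j < pw; ++j) wi += W(i, j) * beta[j];
        double g = y[i] - wi - e[i];
        s1 += g; s2 += g * g;
      }
      double gv = (s2 - s1 * s1 / n) / (n - 1);
      acc_sc += sigma2_c; acc_se += sigma2_e; acc_gv += gv;
      if (n_keep % thin == 0) {
        tr_sc.push_back(sigma2_c);
        tr_se.push_back(sigma2_e);
        tr_gv.push_back(gv);
      }
    }
  }
  for (int k = 0; k < m; ++k) { mf[k] /= n_keep; ceff[k] /= n_keep; }
  for (int j = 0; j < pw; ++j) bmean[j] /= n_keep;
  return List::create(
      _["mf"] = NumericVector(mf.begin(), mf.end()),
      _["effect"] = NumericVector(ceff.begin(), ceff.end()),
      _["fixed_effects"] = NumericVector(bmean.begin(), bmean.end()),
      _["post_sigma2_c"] = acc_sc / n_keep,
      _["post_sigma2_e"] = acc_se / n_keep,
      _["post_genetic_variance"] = acc_gv / n_keep,
      _["trace_sigma2_c"] = NumericVector(tr_sc.begin(), tr_sc.end()),
      _["trace_sigma2_e"] = NumericVector(tr_se.begin(), tr_se.end()),
      _["trace_genetic_variance"] = NumericVector(tr_gv.begin(), tr_gv.end()),
      _["n_samples"] = n_keep);
}
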