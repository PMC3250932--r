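#include <Rcpp.h>
using namespace Rcpp;

// Weighted single-site Gibbs sampler for the BayesC mixture model
//   y_i = mu + sum_j z_ij u_j + e_i,   Var(e_i) = sigma_e^2 / w_i,
//   u_j ~ N(0, sigma_u^2) w.p. (1 - pi), u_j = 0 w.p. pi.
// Markers are updated in fixed (map) order each iteration; the residual
// vector is maintained incrementally. Variances get scaled inverse
// chi-square updates unless held fixed. Uses R's RNG, so set.seed()
// makes chains bitwise reproducible.
//
// batch_size > 0 additionally returns per-marker batch means of u over
// consecutive post-burn-in blocks, for Monte-Carlo standard errors.
// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericMatrix Z, NumericVector y, NumericVector w,
                  double pi_null, int n_iter, int burn_in,
                  double nu_u, double s2_u, double nu_e, double s2_e,
                  double init_var_u, double init_var_e,
                  bool update_var_u, bool update_var_e,
                  int batch_size) {
  const int n = Z.nrow(), m = Z.ncol();
  if (y.size() != n || w.size() != n) stop("dimension mismatch");
  for (int i = 0; i < n; ++i)
    if (!(w[i] > 0)) stop("non-positive weight for record %d", i + 1);
  if (burn_in >= n_iter) stop("burn-in must be shorter than the chain");

  RNGScope scope;

  std::vector<double> u(m, 0.0), e(y.begin(), y.end());
  double mu = 0.0, var_u = init_var_u, var_e = init_var_e;

  // precompute z'Wz per marker
  std::vector<double> zwz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* zj = &Z(0, j);
    for (int i = 0; i < n; ++i) s += w[i] * zj[i] * zj[i];
    zwz[j] = s;
  }
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];

  const double log_prior_odds =
      std::log((1.0 - pi_null)) - std::log(pi_null > 0 ? pi_null : 1e-300);

  const int n_keep = n_iter - burn_in;
  std::vector<double> u_mean(m, 0.0), incl_freq(m, 0.0);
  NumericVector chain_mu(n_keep), chain_var_u(n_keep), chain_var_e(n_keep),
      chain_m_incl(n_keep), chain_var_g(n_keep);

  const int n_batch = (batch_size > 0) ? (n_keep / batch_size) : 0;
  NumericMatrix batch_u(batch_size > 0 ? m : 1, std::max(n_batch, 1));
  std::fill(batch_u.begin(), batch_u.end(), 0.0);

  for (int it = 0; it < n_iter; ++it) {
    // (1) overall mean: weighted normal full conditional
    double swe = 0.0;
    for (int i = 0; i < n; ++i) swe += w[i] * e[i];
    double delta = swe / sw + norm_rand() * std::sqrt(var_e / sw);
    mu += delta;
    for (int i = 0; i < n; ++i) e[i] -= delta;

    // (2) marker effects, fixed order
    int m_incl = 0;
    const double ratio = var_e / var_u;
    for (int j = 0; j < m; ++j) {
      const double* zj = &Z(0, j);
      const double u_old = u[j];
      double zwe = 0.0;
      for (int i = 0; i < n; ++i) zwe += w[i] * zj[i] * e[i];
      const double r_j = zwe + zwz[j] * u_old;
      const double C_j = zwz[j] + ratio;
      if (!(C_j > 0)) stop("non-positive marker precision at locus %d", j + 1);
      const double log_odds = log_prior_odds +
          0.5 * std::log(var_e / (var_u * C_j)) +
          r_j * r_j / (2.0 * var_e * C_j);
      const double p_incl =
          (pi_null <= 0.0) ? 1.0 :
          (pi_null >= 1.0) ? 0.0 :
          1.0 / (1.0 + std::exp(-log_odds));
      double u_new = 0.0;
      if (unif_rand() < p_incl) {
        u_new = r_j / C_j + norm_rand() * std::sqrt(var_e / C_j);
        ++m_incl;
        if (it >= burn_in) incl_freq[j] += 1.0;
      }
      if (u_new != u_old) {
        const double diff = u_old - u_new;
        for (int i = 0; i < n; ++i) e[i] += zj[i] * diff;
        u[j] = u_new;
      }
      if (!std::isfinite(u[j]))
        stop("non-finite marker effect draw at iteration %d", it + 1);
    }

    // (3) common marker-effect variance
    if (update_var_u) {
      double ssu = 0.0;
      int cnt = 0;
      for (int j = 0; j < m; ++j)
        if (u[j] != 0.0) { ssu += u[j] * u[j]; ++cnt; }
      var_u = (nu_u * s2_u + ssu) / ::Rf_rchisq(nu_u + cnt);
    }
    // (4) residual variance (weighted)
    if (update_var_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      var_e = (nu_e * s2_e + sse) / ::Rf_rchisq(nu_e + n);
    }
    if (!std::isfinite(var_u) || !std::isfinite(var_e))
      stop("non-finite variance draw at iteration %d", it + 1);

    if (it >= burn_in) {
      const int k = it - burn_in;
      for (int j = 0; j < m; ++j) u_mean[j] += u[j];
      // genetic values are recoverable from the maintained residual:
      // g_i = y_i - mu - e_i = sum_j z_ij u_j
      double sg = 0.0, sg2 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double g = y[i] - mu - e[i];
        sg += g;
        sg2 += g * g;
      }
      const double vg = (sg2 - sg * sg / n) / (n - 1);
      chain_mu[k] = mu;
      chain_var_u[k] = var_u;
      chain_var_e[k] = var_e;
      chain_m_incl[k] = m_incl;
      chain_var_g[k] = vg;
      if (batch_size > 0 && k / batch_size < n_batch) {
        const int b = k / batch_size;
        for (int j = 0; j < m; ++j) batch_u(j, b) += u[j] / batch_size;
      }
    }
  }

  NumericVector u_hat(m), freq(m);
  for (int j = 0; j < m; ++j) {
    u_hat[j] = u_mean[j] / n_keep;
    freq[j] = incl_freq[j] / n_keep;
  }

  List out = List::create(
      _["u_hat"] = u_hat, _["incl_freq"] = freq,
      _["chain_mu"] = chain_mu, _["chain_var_u"] = chain_var_u,
      _["chain_var_e"] = chain_var_e, _["chain_m_incl"] = chain_m_incl,
      _["chain_var_g"] = chain_var_g);
  if (batch_size > 0) out["batch_u"] = batch_u;
  return out;
}
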