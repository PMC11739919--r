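#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inverse-gamma draw with shape a, rate b (R::rgamma takes shape, scale)
static inline double rinvgamma(double a, double b) {
  double g = R::rgamma(a, 1.0 / b);
  if (g <= 0) g = 1e-300;
  return 1.0 / g;
}

static inline double dot_col(const double* x, const double* y, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i] * y[i];
  return s;
}

// Gibbs sampler for a spike-and-slab Gaussian mixture ("BayesR-style")
// linear model  y = W alpha + X beta + e.
// X: n x p standardized CpG matrix; W: n x q unpenalized covariates
// (including the intercept). gamma: slab variances as fractions of the
// sampled effect-variance scale sigma2_b. Uses R's RNG throughout so that
// set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
List bayesr_gibbs(NumericMatrix X, NumericVector y, NumericMatrix W,
                  NumericVector gamma_frac, int n_iter, int burn_in, int thin,
                  bool force_inclusion = false, double fixed_sigma2_b = -1.0,
                  double scale_prior_shape = 6.0, double scale_prior_mean = 10.0,
                  double dir_spike = 1.0, double dir_slab = 1.0) {
  const int n = X.nrow(), p = X.ncol(), q = W.ncol();
  const int K = gamma_frac.size();           // number of slab components
  if (burn_in >= n_iter) stop("burn_in must be < n_iter");
  if (force_inclusion && K < 1) stop("force_inclusion needs >= 1 slab component");

  // precompute column norms
  std::vector<double> xtx(p), wtw(q);
  for (int j = 0; j < p; ++j) xtx[j] = dot_col(&X(0, j), &X(0, j), n);
  for (int k = 0; k < q; ++k) wtw[k] = dot_col(&W(0, k), &W(0, k), n);

  double ybar = 0.0, vary = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) vary += (y[i] - ybar) * (y[i] - ybar);
  vary /= (n - 1);
  if (vary <= 0) stop("response has zero variance");

  std::vector<double> beta(p, 0.0), alpha(q, 0.0), r(n);
  std::vector<int> comp(p, 0);
  for (int i = 0; i < n; ++i) r[i] = y[i];

  // mixture weights over (spike, slab_1..slab_K)
  std::vector<double> piw(K + 1, 0.0);
  if (force_inclusion) { for (int k = 1; k <= K; ++k) piw[k] = 1.0 / K; }
  else { piw[0] = 0.95; for (int k = 1; k <= K; ++k) piw[k] = 0.05 / K; }

  double sigma2_e = vary * 0.5;
  double sigma2_b = (fixed_sigma2_b > 0) ? fixed_sigma2_b : vary;
  // IG prior on the effect-variance scale (mean scale_prior_mean * var(y)):
  // keeps the smallest slab distinguishable from the spike (if the scale
  // collapses the spike/slab Bayes factor tends to 1 and null CpGs diffuse
  // into the slab)
  const double a_b = scale_prior_shape;
  const double b_b = scale_prior_mean * (scale_prior_shape - 1.0) * vary;
  const double a_e = 0.001, b_e = 0.001;         // IG prior on sigma2_e

  const int keep = (n_iter - burn_in + thin - 1) / thin;
  NumericVector pip(p), beta_sum(p), beta_sq(p);
  NumericVector varexp_draws(keep), sigma2e_draws(keep);
  std::vector<double> comp_prop(K + 1, 0.0);
  std::vector<int> perm(p), nk(K + 1);
  std::vector<double> logp(K + 1), v(K + 1), walpha(n);
  int kept = 0, n_kept_iter = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- unpenalized covariates (flat prior) ---
    for (int k = 0; k < q; ++k) {
      const double* w = &W(0, k);
      double old = alpha[k];
      for (int i = 0; i < n; ++i) r[i] += w[i] * old;
      double rhs = dot_col(w, r.data(), n);
      double mean = rhs / wtw[k];
      double sd = std::sqrt(sigma2_e / wtw[k]);
      alpha[k] = mean + sd * norm_rand();
      for (int i = 0; i < n; ++i) r[i] -= w[i] * alpha[k];
    }

    // --- per-CpG mixture update in random order ---
    for (int j = 0; j < p; ++j) perm[j] = j;
    for (int j = p - 1; j > 0; --j) {
      int u = (int)(unif_rand() * (j + 1));
      if (u > j) u = j;
      std::swap(perm[j], perm[u]);
    }
    std::fill(nk.begin(), nk.end(), 0);
    for (int k = 1; k <= K; ++k) v[k] = gamma_frac[k - 1] * sigma2_b;

    for (int jj = 0; jj < p; ++jj) {
      int j = perm[jj];
      const double* x = &X(0, j);
      if (beta[j] != 0.0) {
        double old = beta[j];
        for (int i = 0; i < n; ++i) r[i] += x[i] * old;
      }
      double rhs = dot_col(x, r.data(), n);
      int kmax = 0;
      double lmax;
      if (force_inclusion) { logp[0] = -1e300; lmax = -1e300; }
      else { logp[0] = std::log(piw[0]); lmax = logp[0]; }
      for (int k = 1; k <= K; ++k) {
        if (piw[k] <= 0.0) { logp[k] = -1e300; continue; }
        double lam = v[k] * xtx[j] / sigma2_e;
        logp[k] = std::log(piw[k]) - 0.5 * std::log1p(lam)
          + 0.5 * v[k] * rhs * rhs / (sigma2_e * (sigma2_e + v[k] * xtx[j]));
        if (logp[k] > lmax) { lmax = logp[k]; kmax = k; }
      }
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) tot += std::exp(logp[k] - lmax);
      double u = unif_rand() * tot, acc = 0.0;
      int pick = kmax;
      for (int k = 0; k <= K; ++k) {
        acc += std::exp(logp[k] - lmax);
        if (u <= acc) { pick = k; break; }
      }
      comp[j] = pick;
      ++nk[pick];
      if (pick == 0) {
        beta[j] = 0.0;
      } else {
        double prec = xtx[j] / sigma2_e + 1.0 / v[pick];
        double mean = (rhs / sigma2_e) / prec;
        double sd = std::sqrt(1.0 / prec);
        beta[j] = mean + sd * norm_rand();
        for (int i = 0; i < n; ++i) r[i] -= x[i] * beta[j];
      }
    }

    // --- mixture weights ~ Dirichlet(counts + 1) ---
    if (!force_inclusion) {
      double s = 0.0;
      for (int k = 0; k <= K; ++k) {
        piw[k] = R::rgamma(nk[k] + (k == 0 ? dir_spike : dir_slab), 1.0);
        s += piw[k];
      }
      for (int k = 0; k <= K; ++k) piw[k] /= s;
    } else if (K > 1) {
      double s = 0.0;
      piw[0] = 0.0;
      for (int k = 1; k <= K; ++k) { piw[k] = R::rgamma(nk[k] + 1.0, 1.0); s += piw[k]; }
      for (int k = 1; k <= K; ++k) piw[k] /= s;
    }

    // --- effect-variance scale ---
    if (fixed_sigma2_b <= 0) {
      double ssq = 0.0; int m = 0;
      for (int j = 0; j < p; ++j) if (comp[j] > 0) {
        ssq += beta[j] * beta[j] / gamma_frac[comp[j] - 1];
        ++m;
      }
      sigma2_b = rinvgamma(a_b + 0.5 * m, b_b + 0.5 * ssq);
    }

    // --- residual variance ---
    double rss = dot_col(r.data(), r.data(), n);
    sigma2_e = rinvgamma(a_e + 0.5 * n, b_e + 0.5 * rss);
    if (!std::isfinite(sigma2_e) || sigma2_e < 1e-12 * vary)
      stop("sampler divergence: residual variance collapsed (iteration %d, sigma2_e=%g)",
           it + 1, sigma2_e);

    // --- accumulate posterior summaries ---
    if (it >= burn_in) {
      ++n_kept_iter;
      for (int j = 0; j < p; ++j) if (comp[j] > 0) pip[j] += 1.0;
      for (int j = 0; j < p; ++j) { beta_sum[j] += beta[j]; beta_sq[j] += beta[j] * beta[j]; }
      for (int k = 0; k <= K; ++k) comp_prop[k] += (double)nk[k] / p;
      if ((it - burn_in) % thin == 0 && kept < keep) {
        // X beta = y - W alpha - r
        for (int i = 0; i < n; ++i) walpha[i] = 0.0;
        for (int k = 0; k < q; ++k) {
          const double* w = &W(0, k);
          for (int i = 0; i < n; ++i) walpha[i] += w[i] * alpha[k];
        }
        double gm = 0.0;
        for (int i = 0; i < n; ++i) gm += y[i] - walpha[i] - r[i];
        gm /= n;
        double gv = 0.0;
        for (int i = 0; i < n; ++i) {
          double gi = y[i] - walpha[i] - r[i] - gm;
          gv += gi * gi;
        }
        gv /= (n - 1);
        varexp_draws[kept] = gv / vary;
        sigma2e_draws[kept] = sigma2_e;
        ++kept;
      }
    }
  }

  for (int j = 0; j < p; ++j) {
    pip[j] /= n_kept_iter;
    beta_sum[j] /= n_kept_iter;
    double m2 = beta_sq[j] / n_kept_iter - beta_sum[j] * beta_sum[j];
    beta_sq[j] = std::sqrt(m2 > 0 ? m2 : 0);
  }
  NumericVector cp(K + 1);
  for (int k = 0; k <= K; ++k) cp[k] = comp_prop[k] / n_kept_iter;

  return List::create(
    _["pip"] = pip, _["beta_mean"] = beta_sum, _["beta_sd"] = beta_sq,
    _["component_proportions"] = cp,
    _["varexp_draws"] = varexp_draws[Range(0, kept - 1)],
    _["sigma2e_draws"] = sigma2e_draws[Range(0, kept - 1)],
    _["final_beta"] = NumericVector(beta.begin(), beta.end()),
    _["final_alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["final_residual"] = NumericVector(r.begin(), r.end()));
}
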