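#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inverse-gamma draw via R's gamma RNG (shape/scale parameterisation).
static inline double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0.0) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

// Gibbs sampler for the Gaussian phylogenetic mixed model
//   y = X beta + sum_k alpha_k Z_k eta_k + e,
// with parameter expansion on each random term: eta_k ~ N(0, s2eta_k G_k),
// alpha_k ~ N(exp_mean, exp_var); the reported variance component is
// alpha_k^2 * s2eta_k. G_k is A (phylogeny) or I (species/colony);
// Z_k is an incidence map from records to group levels.
//
// Sweep order (fixed): beta; then per random term eta_k followed by its
// working scalar alpha_k; then each s2eta_k; then the residual variance.
// A single R RNG stream drives the whole chain (seed it with set.seed()).
// [[Rcpp::export]]
List gibbs_pmm_cpp(const arma::vec& y,
                   const arma::mat& X,
                   const List& terms,
                   const arma::vec& beta_prior_var,
                   double re_scale, double re_df,
                   double exp_mean, double exp_var,
                   double resid_scale, double resid_df,
                   double resid_fixed,   // <= 0 => sample the residual var
                   int n_iter, int burn_in, int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = terms.size();
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("chain config error: retained draw count is 0");

  // unpack random terms
  std::vector<arma::uvec> map(K);     // 0-based record -> level
  std::vector<int> q(K);
  std::vector<bool> has_A(K);
  std::vector<arma::mat> Ainv(K);
  std::vector<arma::vec> ng(K);       // records per level
  for (int k = 0; k < K; ++k) {
    List tk = terms[k];
    IntegerVector m = tk["map"];
    int qk = as<int>(tk["q"]);
    arma::uvec mk(n);
    for (int i = 0; i < n; ++i) mk[i] = m[i] - 1;
    map[k] = mk; q[k] = qk;
    arma::vec cnt(qk, arma::fill::zeros);
    for (int i = 0; i < n; ++i) cnt[mk[i]] += 1.0;
    ng[k] = cnt;
    SEXP Ai = tk["Ainv"];
    if (Rf_isNull(Ai)) { has_A[k] = false; }
    else { has_A[k] = true; Ainv[k] = as<arma::mat>(Ai); }
  }

  const arma::mat XtX = X.t() * X;
  const bool fix_resid = resid_fixed > 0.0;

  // state
  arma::vec beta(p, arma::fill::zeros);
  std::vector<arma::vec> eta(K);
  std::vector<double> alpha(K, 1.0), s2eta(K, re_scale);
  for (int k = 0; k < K; ++k) eta[k] = arma::vec(q[k], arma::fill::zeros);
  double s2e = fix_resid ? resid_fixed : arma::var(y);
  if (s2e <= 0.0) s2e = 1.0;

  // storage
  arma::mat beta_keep(n_keep, p);
  arma::mat sig_keep(n_keep, K + 1);
  arma::vec dev_keep(n_keep);
  std::vector<arma::mat> u_keep(K);
  for (int k = 0; k < K; ++k) u_keep[k] = arma::mat(n_keep, q[k]);

  arma::vec zvec, r(n), t, fit_random(n, arma::fill::zeros);
  int keep_i = 0;

  // per-record random-effect contribution of term k: alpha_k * eta_k[map]
  auto term_contrib = [&](int k, arma::vec& out) {
    for (int i = 0; i < n; ++i) out[i] = alpha[k] * eta[k][map[k][i]];
  };

  std::vector<arma::vec> w(K, arma::vec(n, arma::fill::zeros));

  for (int it = 1; it <= n_iter; ++it) {
    // --- fixed effects ---
    fit_random.zeros();
    for (int k = 0; k < K; ++k) { term_contrib(k, w[k]); fit_random += w[k]; }
    r = y - fit_random;
    arma::mat P = XtX / s2e;
    for (int j = 0; j < p; ++j) P(j, j) += 1.0 / beta_prior_var[j];
    arma::vec b = X.t() * r / s2e;
    arma::mat U;
    if (!arma::chol(U, P)) stop("non-finite conditional precision for fixed effects at iteration %d", it);
    // mean = P^{-1} b; draw = mean + U^{-1} z
    arma::vec mean_b = arma::solve(arma::trimatu(U),
                                   arma::solve(arma::trimatl(U.t()), b));
    zvec = arma::vec(p);
    for (int j = 0; j < p; ++j) zvec[j] = norm_rand();
    beta = mean_b + arma::solve(arma::trimatu(U), zvec);
    if (!beta.is_finite()) stop("non-finite fixed-effect draw at iteration %d", it);

    arma::vec xb = X * beta;

    // --- random terms: eta then alpha ---
    for (int k = 0; k < K; ++k) {
      // residual excluding this term
      r = y - xb;
      for (int j = 0; j < K; ++j) if (j != k) r -= w[j];
      // per-level sums of r
      t = arma::vec(q[k], arma::fill::zeros);
      for (int i = 0; i < n; ++i) t[map[k][i]] += r[i];
      double a2 = alpha[k] * alpha[k];
      if (has_A[k]) {
        arma::mat M = Ainv[k] / s2eta[k];
        for (int g = 0; g < q[k]; ++g) M(g, g) += a2 * ng[k][g] / s2e;
        arma::mat Uk;
        if (!arma::chol(Uk, M)) stop("non-finite conditional precision for random term at iteration %d", it);
        arma::vec bk = (alpha[k] / s2e) * t;
        arma::vec mk = arma::solve(arma::trimatu(Uk),
                                   arma::solve(arma::trimatl(Uk.t()), bk));
        zvec = arma::vec(q[k]);
        for (int g = 0; g < q[k]; ++g) zvec[g] = norm_rand();
        eta[k] = mk + arma::solve(arma::trimatu(Uk), zvec);
      } else {
        for (int g = 0; g < q[k]; ++g) {
          double prec = a2 * ng[k][g] / s2e + 1.0 / s2eta[k];
          double mg = (alpha[k] * t[g] / s2e) / prec;
          eta[k][g] = mg + norm_rand() / std::sqrt(prec);
        }
      }
      if (!eta[k].is_finite()) stop("non-finite random-effect draw at iteration %d", it);

      // working scalar regression coefficient
      double sww = 0.0, swr = 0.0;
      for (int g = 0; g < q[k]; ++g) {
        sww += ng[k][g] * eta[k][g] * eta[k][g];
        swr += eta[k][g] * t[g];
      }
      double prec_a = sww / s2e + 1.0 / exp_var;
      double mean_a = (swr / s2e + exp_mean / exp_var) / prec_a;
      alpha[k] = mean_a + norm_rand() / std::sqrt(prec_a);
      term_contrib(k, w[k]);
    }

    // --- variance components ---
    for (int k = 0; k < K; ++k) {
      double ss;
      if (has_A[k]) ss = arma::as_scalar(eta[k].t() * Ainv[k] * eta[k]);
      else ss = arma::dot(eta[k], eta[k]);
      s2eta[k] = rinvgamma((re_df + q[k]) / 2.0,
                           (re_df * re_scale + ss) / 2.0);
    }
    fit_random.zeros();
    for (int k = 0; k < K; ++k) fit_random += w[k];
    arma::vec e = y - xb - fit_random;
    double sse = arma::dot(e, e);
    if (!fix_resid) {
      s2e = rinvgamma((resid_df + n) / 2.0,
                      (resid_df * resid_scale + sse) / 2.0);
    }

    // --- retain ---
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_keep(keep_i, j) = beta[j];
      for (int k = 0; k < K; ++k)
        sig_keep(keep_i, k) = alpha[k] * alpha[k] * s2eta[k];
      sig_keep(keep_i, K) = s2e;
      double dev = n * std::log(2.0 * M_PI * s2e) + sse / s2e;
      if (!std::isfinite(dev)) stop("non-finite deviance at iteration %d", it);
      dev_keep[keep_i] = dev;
      for (int k = 0; k < K; ++k)
        for (int g = 0; g < q[k]; ++g)
          u_keep[k](keep_i, g) = alpha[k] * eta[k][g];
      ++keep_i;
    }
  }

  List u_out(K);
  for (int k = 0; k < K; ++k) u_out[k] = u_keep[k];
  return List::create(_["beta"] = beta_keep, _["sigma2"] = sig_keep,
                      _["deviance"] = dev_keep, _["u"] = u_out);
}
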