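# Shared fixtures and oracles for the test suite. All fixtures are built in
# code; no binary files.

# Three hand-readable records (one absent brood_size / breeding_pairs).
make_obs3 <- function() {
  validate_fmr(data.frame(
    record_id = c("r1", "r2", "r3"),
    study_id = c("s1", "s1", "s2"),
    species = c("Pygoscelis adeliae", "Uria aalge", "Sula bassana"),
    colony = c("ColA", "ColB", "ColC"),
    latitude_deg = c(-64.8, 58.1, 55.9),
    phase = c("brood", "incubation", "creche"),
    mass_g = c(4000, 990, 3000),
    fmr_kj_day = c(4100, 1950, 4800),
    brood_size = c(2, 1, NA),
    breeding_pairs = c(120000, 30000, NA),
    stringsAsFactors = FALSE))
}

write_newick_tmp <- function(txt) {
  path <- tempfile(fileext = ".nwk")
  writeLines(txt, path)
  path
}

tree_from_text <- function(txt) read_newick(write_newick_tmp(txt))

# Short chain for smoke-level fits.
fast_chain <- function(seed = 1, n_iter = 3000, burn_in = 500, thin = 5) {
  chain_config(n_iter, burn_in, thin, seed = seed)
}

# Small synthetic world used across sampler/prediction tests.
small_sim <- function(seed = 10, n_species = 8, n_records = 40,
                      truth = NULL) {
  if (is.null(truth)) {
    truth <- ground_truth(
      beta = c(intercept = 0.9, log_mass = 0.64,
               phase_incubation = -0.07, phase_creche = 0.07,
               abs_latitude = 0.005),
      sigma2 = c(phylogeny = 0.004, species = 0.006, colony = 0.004,
                 residual = 0.02))
  }
  tree <- simulate_tree(n_species, seed = seed)
  sim <- simulate_observations(tree, truth, n_records, seed = seed + 1L)
  list(obs = sim$observations, tree = tree, A = tree_to_correlation(tree),
       truth = truth, effects = sim$effects)
}

# Independent brute-force HPD oracle: enumerate every contiguous window.
hpd_brute <- function(draws, prob = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(prob * n)
  best <- c(s[1], s[m])
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1] - 1e-15) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# Posterior degenerate at the published coefficient table (base 10), used
# by the prediction arithmetic tests.
table1_posterior <- function(n_draws = 20) {
  beta <- matrix(rep(c(0.92, -0.071, 0.068, 0.64, 0.0048), each = n_draws),
                 nrow = n_draws,
                 dimnames = list(NULL, c("intercept", "phase_incubation",
                                         "phase_creche", "log_mass",
                                         "abs_latitude")))
  sigma2 <- matrix(1e-12, n_draws, 1, dimnames = list(NULL, "residual"))
  fmr_posterior(beta = beta, sigma2 = sigma2, meta = list(log_base = 10))
}

# Conjugate posterior for known-variance Gaussian regression with
# independent N(0, vb) coefficient priors: the analytic oracle.
conjugate_posterior <- function(X, y, s2, vb) {
  P <- crossprod(X) / s2 + diag(1 / vb, ncol(X))
  V <- solve(P)
  list(mean = as.numeric(V %*% crossprod(X, y) / s2), cov = V)
}
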