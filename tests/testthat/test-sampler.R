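test_that("build_design lays out incidence structure per the spec", {
  obs <- validate_fmr(data.frame(
    record_id = paste0("r", 1:5), study_id = "s",
    species = c("A a", "A a", "B b", "B b", "C c"),
    colony = c("c1", "c1", "c2", "c2", "c2"),
    latitude_deg = c(10, 20, -30, 40, 55),
    phase = c("brood", "incubation", "creche", "brood", "incubation"),
    mass_g = c(100, 120, 300, 310, 500),
    fmr_kj_day = c(200, 210, 400, 390, 800),
    brood_size = c(1, 1, 2, 2, 3),
    breeding_pairs = c(1000, 1000, 2000, 2000, 500)))
  tree <- tree_from_text("((A_a:1,B_b:1):1,C_c:2);")
  A <- tree_to_correlation(tree)
  spec <- model_spec(fixed = c("log_mass", "phase", "abs_latitude",
                               "brood_size", "log_rpp"),
                     chain = fast_chain())
  d <- build_design(obs, spec, A = A)
  expect_equal(colnames(d$X),
               c("intercept", "log_mass", "phase_incubation", "phase_creche",
                 "abs_latitude", "brood_size", "log_rpp"))
  expect_equal(length(d$y), 5L)
  # one level per species/colony, one membership per record
  expect_equal(length(d$terms$species$labels), 3L)
  expect_equal(tabulate(d$terms$species$map), c(2L, 2L, 1L))
  expect_equal(d$terms$phylogeny$map, d$terms$species$map)
  expect_equal(dim(d$terms$phylogeny$A), c(3L, 3L))
  # colony grouping keys on the colony name
  expect_equal(length(d$terms$colony$labels), 2L)

  spec2 <- model_spec(random = c("species", "colony"), chain = fast_chain())
  d2 <- build_design(obs, spec2)
  expect_null(d2$terms$phylogeny)

  obs_bad <- obs; obs_bad$species[5] <- "Zz yy"
  expect_error(build_design(obs_bad, spec, A = A), "missing.*Zz_yy")

  obs_const <- obs; obs_const$phase <- "brood"
  expect_error(build_design(obs_const, spec, A = A),
               "constant|unidentifiable")
})

test_that("a fixed seed makes the sampler fully deterministic", {
  s <- small_sim(seed = 21, n_records = 60)
  spec <- model_spec(chain = fast_chain(seed = 99))
  d <- build_design(s$obs, spec, A = s$A)
  f1 <- suppressMessages(gibbs_fit(d))
  f2 <- suppressMessages(gibbs_fit(d))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$deviance, f2$deviance)
  expect_equal(nrow(f1$beta), spec$chain$retained)
  expect_true(all(f1$sigma2 > 0))
  expect_true(all(is.finite(f1$deviance)))
})

test_that("with known residual variance the sampler matches the conjugate oracle", {
  s <- small_sim(seed = 31)
  s2_true <- 0.25
  vb <- 1e8
  spec <- model_spec(fixed = "log_mass", random = character(0),
                     priors = prior_spec(residual_fixed = s2_true,
                                         fixed_effect_prior_var = vb),
                     chain = chain_config(5200, 200, 1, seed = 7))
  d <- build_design(s$obs, spec)
  fit <- gibbs_fit(d)
  an <- conjugate_posterior(d$X, d$y, s2_true, vb)
  nd <- nrow(fit$beta)
  for (j in seq_len(ncol(d$X))) {
    mcse <- sqrt(an$cov[j, j] / nd)  # draws are iid here
    expect_lt(abs(mean(fit$beta[, j]) - an$mean[j]), 3 * mcse)
    expect_lt(abs(var(fit$beta[, j]) - an$cov[j, j]),
              3 * an$cov[j, j] * sqrt(2 / (nd - 1)))
  }
  # intercept-only variant: posterior mean equals the sample mean of y
  spec0 <- model_spec(fixed = character(0), random = character(0),
                      priors = prior_spec(residual_fixed = s2_true,
                                          fixed_effect_prior_var = 1e10),
                      chain = chain_config(5200, 200, 1, seed = 8))
  d0 <- build_design(s$obs, spec0)
  fit0 <- gibbs_fit(d0)
  mcse0 <- sqrt(s2_true / length(d0$y) / nrow(fit0$beta))
  expect_lt(abs(mean(fit0$beta[, "intercept"]) - mean(d0$y)), 3 * mcse0)
})

test_that("with variances sampled and flat priors the posterior matches OLS", {
  s <- small_sim(seed = 41, n_records = 60)
  spec <- model_spec(fixed = c("log_mass", "abs_latitude"),
                     random = character(0),
                     priors = prior_spec(fixed_effect_prior_var = 1e10),
                     chain = chain_config(6000, 1000, 1, seed = 5))
  d <- build_design(s$obs, spec)
  fit <- gibbs_fit(d)
  ols <- stats::lm.fit(d$X, d$y)
  for (j in seq_len(ncol(d$X))) {
    draws <- fit$beta[, j]
    mcse <- sd(draws) / sqrt(autocorrelation(draws)$ess)
    expect_lt(abs(mean(draws) - ols$coefficients[j]), 3 * mcse)
  }
})

test_that("permuting observation order leaves the posterior unchanged", {
  s <- small_sim(seed = 51, n_records = 50)
  spec <- model_spec(chain = chain_config(6000, 1000, 5, seed = 17))
  d1 <- build_design(s$obs, spec, A = s$A)
  set.seed(3)
  perm <- sample(nrow(s$obs))
  d2 <- build_design(s$obs[perm, ], spec, A = s$A)
  f1 <- suppressMessages(gibbs_fit(d1))
  f2 <- suppressMessages(gibbs_fit(d2))
  for (j in colnames(f1$beta)) {
    m1 <- mean(f1$beta[, j]); m2 <- mean(f2$beta[, j])
    mcse <- sqrt(sd(f1$beta[, j])^2 / autocorrelation(f1$beta[, j])$ess +
                   sd(f2$beta[, j])^2 / autocorrelation(f2$beta[, j])$ess)
    expect_lt(abs(m1 - m2), 4 * mcse)
  }
})

test_that("degenerate configs error cleanly", {
  s <- small_sim(seed = 61)
  expect_error(chain_config(1000, 1000, 10), "burn_in")
  spec <- model_spec(chain = chain_config(1000, 990, 50, seed = 1))
  expect_equal(spec$chain$retained, 0L)
  d <- build_design(s$obs, spec, A = s$A)
  expect_error(suppressMessages(gibbs_fit(d)), "retained draw count is 0")
  expect_error(build_design(s$obs, model_spec(chain = fast_chain())),
               "requires a phylo_correlation")
})

test_that("posterior serialization round-trips draws and metadata", {
  s <- small_sim(seed = 71)
  spec <- model_spec(chain = fast_chain(seed = 2, n_iter = 1500,
                                        burn_in = 300))
  d <- build_design(s$obs, spec, A = s$A)
  fit <- suppressMessages(gibbs_fit(d))
  dir <- tempfile()
  write_posterior(fit, dir)
  back <- read_posterior(dir)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colnames(back$sigma2), colnames(fit$sigma2))
  expect_equal(back$deviance, fit$deviance, tolerance = 1e-12)
  expect_equal(back$meta$log_base, 10)
  expect_equal(sort(names(back$u)), sort(names(fit$u)))
})

test_that("A-structured variance posterior matches a grid-integration oracle", {
  # phylogeny + residual model, intercept only: beta can be integrated out
  # analytically, leaving a 2-D posterior over the variances that a dense
  # grid evaluates independently of the Gibbs machinery.
  tree <- simulate_tree(10, seed = 55)
  truth <- ground_truth(beta = c(intercept = 1),
                        sigma2 = c(phylogeny = 0.002, species = 0,
                                   colony = 0, residual = 0.03))
  sim <- simulate_observations(tree, truth, 30, seed = 56)
  pc <- tree_to_correlation(tree)
  spec <- model_spec(fixed = character(0), random = "phylogeny",
                     chain = chain_config(52000, 2000, 10, seed = 9))
  d <- build_design(sim$observations, spec, A = pc)
  fit <- suppressMessages(gibbs_fit(d))
  h2_samp <- mean(fit$sigma2[, "phylogeny"] /
                    (fit$sigma2[, "phylogeny"] + fit$sigma2[, "residual"]))

  y <- as.numeric(d$y); n <- length(y)
  Z <- matrix(0, n, 10)
  for (i in seq_len(n)) Z[i, d$terms$phylogeny$map[i]] <- 1
  AZ <- Z %*% d$terms$phylogeny$A %*% t(Z)
  X <- d$X; vb <- 1e8
  loglik <- function(vp, ve) {
    S <- vp * AZ + ve * diag(n) + vb * tcrossprod(X)
    ch <- chol(S)
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
  }
  # induced parameter-expansion prior: sd ~ half-Cauchy(sqrt(expansion_var))
  lp_v <- function(v) -log(pi) - 0.5 * log(625 * v) - log1p(v / 625)
  lp_e <- function(v) {
    a <- 0.001; b <- 0.001  # IG(nu/2, nu V/2) with nu = 0.002, V = 1
    a * log(b) - lgamma(a) - (a + 1) * log(v) - b / v
  }
  vp_grid <- exp(seq(log(1e-6), log(5), length.out = 160))
  ve_grid <- exp(seq(log(0.003), log(0.4), length.out = 140))
  lw <- outer(vp_grid, ve_grid, Vectorize(function(vp, ve)
    loglik(vp, ve) + lp_v(vp) + lp_e(ve) + log(vp) + log(ve)))
  w <- exp(lw - max(lw)); w <- w / sum(w)
  e_vp <- sum(w * vp_grid)
  e_ve <- sum(sweep(w, 2, ve_grid, "*"))
  e_h2 <- sum(w * outer(vp_grid, ve_grid, function(a, b) a / (a + b)))

  expect_equal(mean(fit$sigma2[, "phylogeny"]), e_vp, tolerance = 0.1)
  expect_equal(mean(fit$sigma2[, "residual"]), e_ve, tolerance = 0.05)
  expect_lt(abs(h2_samp - e_h2), 0.03)
})
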