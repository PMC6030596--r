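test_that("hpd_interval matches frozen hand-enumerated cases", {
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  expect_equal(hpd_interval(c(-2, -1, 0, 1, 2), 0.6),
               c(lower = -2, upper = 0))
  expect_equal(hpd_interval(rep(3.5, 20)), c(lower = 3.5, upper = 3.5))
  expect_error(hpd_interval(3), "at least 2")
})

test_that("hpd_interval equals brute-force window search (property)", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    draws <- switch(1 + i %% 3,
                    rnorm(n), rexp(n), rlnorm(n, sdlog = 1.5))
    prob <- runif(1, 0.5, 0.99)
    expect_equal(unname(hpd_interval(draws, prob)), hpd_brute(draws, prob))
  }
})

test_that("p_mcmc follows the two-tailed sign-fraction convention", {
  expect_equal(p_mcmc(c(rep(1, 500), rep(-1, 500))), 1.0)
  expect_equal(p_mcmc(rep(1, 1000)), 0.002)
  expect_equal(p_mcmc(c(rep(1, 950), rep(-1, 50))), 0.1)
  set.seed(1)
  d <- rnorm(200, 0.3)
  expect_equal(p_mcmc(d * 7.3), p_mcmc(d))   # positive rescale invariant
  expect_equal(p_mcmc(-d), p_mcmc(d))        # two-tailed: sign-symmetric
})

test_that("heritability is the phylogenetic share of total random variance", {
  m <- matrix(1, 10, 4,
              dimnames = list(NULL, c("phylogeny", "species", "colony",
                                      "residual")))
  h <- heritability(m)
  expect_equal(h$h2, rep(0.25, 10))
  m2 <- m; m2[, "phylogeny"] <- 3
  expect_equal(heritability(m2)$h2, rep(0.5, 10))
  m3 <- m; m3[, "phylogeny"] <- 0
  expect_equal(heritability(m3)$h2, rep(0, 10))
  expect_error(heritability(m[, -1, drop = FALSE]), "phylogeny")
  # H2 in [0,1] for arbitrary positive draws
  set.seed(2)
  m4 <- matrix(rexp(400), 100, 4, dimnames = dimnames(m))
  expect_true(all(heritability(m4)$h2 >= 0 & heritability(m4)$h2 <= 1))
})

test_that("DIC reduces to the deviance in the zero-complexity limit", {
  s <- small_sim(seed = 81)
  spec <- model_spec(fixed = "log_mass", random = character(0),
                     chain = fast_chain())
  d <- build_design(s$obs, spec)
  b <- c(intercept = 0.5, log_mass = 0.6)
  s2 <- 0.04
  n <- length(d$y)
  dev <- n * log(2 * pi * s2) + sum((d$y - d$X %*% b)^2) / s2
  fit <- fmr_posterior(
    beta = matrix(rep(b, each = 20), 20, dimnames = list(NULL, names(b))),
    sigma2 = matrix(s2, 20, 1, dimnames = list(NULL, "residual")),
    deviance = rep(dev, 20), design = d, meta = list(log_base = 10))
  res <- compute_dic(fit)
  expect_equal(res$dic, dev, tolerance = 1e-10)
  expect_equal(res$pd, 0, tolerance = 1e-10)
})

test_that("autocorrelation and ESS behave on known series", {
  set.seed(7)
  n <- 2000
  white <- rnorm(n)
  ac <- autocorrelation(white, max_lag = 20)
  expect_lt(abs(ac$acf[["1"]]), 3 / sqrt(n))
  expect_equal(ac$acf[["0"]], 1)

  paired <- rep(rnorm(n / 2), each = 2)  # analytic lag-1 rho = 1/2
  expect_lt(abs(autocorrelation(paired)$ess - n / 2), 0.15 * n / 2)

  expect_warning(res <- autocorrelation(rep(1, 100)), "constant")
  expect_equal(res$ess, 100)
  expect_error(autocorrelation(rnorm(20)), "at least 50")
})

test_that("jackknife of the mean matches its closed form", {
  # intercept-only, fixed residual variance, flat prior: the posterior mean
  # is the leave-one-out sample mean, so the jackknife has a closed form.
  obs <- validate_fmr(data.frame(
    record_id = c("r1", "r2", "r3"), study_id = "s",
    species = "A a", colony = "c", latitude_deg = 0,
    phase = "brood", mass_g = 1000,
    fmr_kj_day = 10^c(1, 2, 3),  # y = log10 fmr = 1, 2, 3
    brood_size = 1, breeding_pairs = 100))
  spec <- model_spec(fixed = character(0), random = character(0),
                     priors = prior_spec(residual_fixed = 0.1,
                                         fixed_effect_prior_var = 1e10),
                     chain = chain_config(4200, 200, 1, seed = 3))
  jk <- jackknife(obs, spec, chain = spec$chain)
  loo <- jk$estimates[, "intercept"]
  mcse <- sqrt(0.1 / 2) / sqrt(4000)
  expect_lt(abs(loo[["r1"]] - 2.5), 3 * mcse)
  expect_lt(abs(loo[["r2"]] - 2.0), 3 * mcse)
  expect_lt(abs(loo[["r3"]] - 1.5), 3 * mcse)
  expect_lt(abs(jk$se[["intercept"]] - sqrt(2 / 3 * 0.5)), 0.05)
  expect_error(jackknife(obs[1:2, ], spec), "at least 3")
})

test_that("model_selection tabulates DIC with simplicity tie-break", {
  s <- small_sim(seed = 91, n_records = 40)
  chain <- fast_chain(seed = 4, n_iter = 2000, burn_in = 400)
  sp1 <- model_spec(fixed = "log_mass", random = "species", chain = chain)
  sp2 <- model_spec(fixed = c("log_mass", "abs_latitude"),
                    random = "species", chain = chain)
  comp <- model_selection(list(sp1, sp2), s$obs)
  expect_s3_class(comp, "fmr_model_comparison")
  expect_equal(sum(comp$best), 1L)
  expect_equal(min(comp$delta_dic), 0)
  expect_true(all(comp$delta_dic >= 0))
  # identical candidates share a seed, so their DIC ties exactly and the
  # tie-break still marks exactly one best model
  comp2 <- model_selection(list(sp1, sp1), s$obs)
  expect_equal(comp2$delta_dic, c(0, 0))
  expect_equal(sum(comp2$best), 1L)
  expect_error(model_selection(list(sp1), s$obs), "at least 2")
})

test_that("summarize_fit produces the publication-table layout", {
  # degenerate posterior: mean = value, zero-width HPD, floored pMCMC
  fit <- table1_posterior(50)
  sm <- summarize_fit(fit)
  eff <- sm$effects
  expect_equal(eff$estimate[eff$effect == "log_mass"], 0.64)
  expect_equal(eff$lower_95, eff$upper_95)
  expect_equal(eff$p_mcmc[eff$effect == "intercept"], 2 / 50)
  expect_null(sm$h2)  # no phylogeny component in this fit

  s <- small_sim(seed = 101)
  spec <- model_spec(chain = fast_chain(seed = 5))
  fit2 <- suppressMessages(gibbs_fit(build_design(s$obs, spec, A = s$A)))
  sm2 <- summarize_fit(fit2)
  expect_true(sm2$h2[["mean"]] >= 0 && sm2$h2[["mean"]] <= 1)
  expect_true(is.finite(sm2$dic$dic))
  expect_equal(sm2$n_draws, spec$chain$retained)

  path <- tempfile(fileext = ".csv")
  write_fit_summary(sm2, path)
  lines <- readLines(path)
  expect_match(lines[1], "effect.*estimate.*lower_95.*upper_95.*p_mcmc")
  expect_true(any(grepl("^H2_mean,", lines)))
  expect_true(any(grepl("^DIC,", lines)))
})
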