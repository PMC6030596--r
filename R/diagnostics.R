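#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(prob * n)` draws; ties are broken by the lowest start index, so
#' results are bit-stable.
#'
#' @param draws numeric sample (at least 2 draws; posterior summaries use
#'   far more).
#' @param prob interval mass, in (0, 1).
#' @return named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 2L) stop("hpd_interval requires at least 2 draws", call. = FALSE)
  stopifnot(prob > 0, prob < 1)
  s <- sort(draws)
  m <- ceiling(prob * n)
  if (m > n) stop("fewer draws than required window", call. = FALSE)
  starts <- seq_len(n - m + 1L)
  widths <- s[starts + m - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first minimum: lowest start
  c(lower = s[i], upper = s[i + m - 1L])
}

#' Two-tailed MCMC sign probability (pMCMC)
#'
#' `2 * min(fraction of draws > 0, fraction < 0)`, floored at `2/n` and
#' capped at 1 — the two-tailed sign-fraction convention of the mixed-model
#' MCMC literature, where a table entry of "<0.001" reflects the floor.
#'
#' @param draws numeric sample (at least 10 draws).
#' @return probability in (0, 1\].
#' @export
p_mcmc <- function(draws) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 10L) stop("p_mcmc requires at least 10 draws", call. = FALSE)
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  min(max(p, 2 / n), 1)
}

#' Phylogenetic heritability from variance-component draws
#'
#' Per draw, `H2 = sigma2_phylo / (sigma2_phylo + sigma2_species +
#' sigma2_colony + sigma2_residual)`; random terms absent from the fit
#' contribute zero. Fixed-effect variance is excluded from the denominator
#' (H2 indexes the proportion of *random* variance attributable to
#' phylogeny).
#'
#' @param sigma2 matrix of variance-component draws with a `phylogeny`
#'   column (e.g. `fit$sigma2`).
#' @return list with `h2` (per-draw values), `mean`, and `sd`.
#' @export
heritability <- function(sigma2) {
  sigma2 <- as.matrix(sigma2)
  if (!"phylogeny" %in% colnames(sigma2)) {
    stop("heritability requires a 'phylogeny' variance component",
         call. = FALSE)
  }
  if (any(sigma2 < 0)) stop("variance draws must be non-negative")
  keep <- intersect(c(RANDOM_TERMS, "residual"), colnames(sigma2))
  denom <- rowSums(sigma2[, keep, drop = FALSE])
  h2 <- sigma2[, "phylogeny"] / denom
  list(h2 = h2, mean = mean(h2), sd = sd(h2))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the mean conditional deviance over retained
#' draws and `pD = Dbar - D(posterior-mean parameters)`; the deviance is
#' conditional on the realized random effects, matching what the sampler
#' records. Negative `pD` is reported with a warning, never clipped.
#'
#' @param fit an `fmr_posterior` carrying its design bundle.
#' @return list with `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "fmr_posterior"))
  if (is.null(fit$design)) {
    stop("DIC requires the design bundle (fit produced by gibbs_fit)",
         call. = FALSE)
  }
  if (is.null(fit$deviance)) stop("fit has no deviance draws", call. = FALSE)
  design <- fit$design
  n <- length(design$y)
  beta_bar <- colMeans(fit$beta)
  mu <- as.numeric(design$X %*% beta_bar)
  for (nm in names(design$terms)) {
    u_bar <- colMeans(fit$u[[nm]])
    mu <- mu + u_bar[design$terms[[nm]]$map]
  }
  s2e_bar <- mean(fit$sigma2[, "residual"])
  dhat <- n * log(2 * pi * s2e_bar) + sum((design$y - mu)^2) / s2e_bar
  if (!is.finite(dhat)) {
    stop("non-finite deviance at posterior-mean parameters", call. = FALSE)
  }
  dbar <- mean(fit$deviance)
  pd <- dbar - dhat
  if (pd < 0) warning(sprintf("negative pD (%.3f); reported unclipped", pd),
                      call. = FALSE)
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Chain autocorrelation and effective sample size
#'
#' Normalized autocovariance at lags `0..max_lag` plus an effective sample
#' size computed by initial-positive-sequence truncation of the
#' autocorrelation sum: `ESS = n / (1 + 2 * sum(rho_k))`, summing
#' consecutive lags until the first non-positive autocorrelation.
#'
#' @param draws numeric chain (at least 50 draws).
#' @param max_lag largest lag to evaluate.
#' @return list with `acf` (named vector, lags 0..max_lag) and `ess`.
#' @export
autocorrelation <- function(draws, max_lag = min(50L, length(draws) - 1L)) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 50L) stop("autocorrelation requires at least 50 draws",
                    call. = FALSE)
  stopifnot(max_lag >= 1, max_lag < n)
  if (sd(draws) == 0) {
    warning("constant chain: autocorrelation undefined, ESS set to n",
            call. = FALSE)
    rho <- c(1, rep(NA_real_, max_lag))
    names(rho) <- 0:max_lag
    return(list(acf = rho, ess = n))
  }
  rho <- as.numeric(acf(draws, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
  names(rho) <- 0:max_lag
  s <- 0
  for (k in 2:(max_lag + 1L)) {
    if (is.na(rho[k]) || rho[k] <= 0) break
    s <- s + rho[k]
  }
  list(acf = rho, ess = n / (1 + 2 * s))
}

#' Jackknife resampling of the model fit
#'
#' Refits the model `n` times, each leaving out one observation record, and
#' returns the per-refit posterior means of the fixed effects, their
#' jackknife mean, and the jackknife standard error
#' `sqrt((n - 1)/n * sum((theta_i - theta_bar)^2))`. A failing refit is
#' recorded as missing with its reason, not fatal. Refits default to a
#' reduced chain (26 000 / 6 000 / 20) for tractability.
#'
#' @param observations validated `fmr_data` table with at least 3 records.
#' @param spec a [model_spec()].
#' @param A optional `phylo_correlation` (required if the spec has a
#'   phylogeny term).
#' @param chain chain schedule for the refits.
#' @return object of class `fmr_jackknife`: list with `estimates` (n x p
#'   matrix of leave-one-out posterior means, NA rows for failures), `mean`,
#'   `se`, and `failures` (named reasons).
#' @export
jackknife <- function(observations, spec, A = NULL,
                      chain = chain_config(26000, 6000, 20,
                                           seed = spec$chain$seed)) {
  obs <- validate_fmr(as.data.frame(observations))
  n <- nrow(obs)
  if (n < 3L) stop("jackknife requires at least 3 records", call. = FALSE)
  spec_jk <- spec
  spec_jk$chain <- chain
  p_names <- expand_fixed_terms(spec$fixed_terms)
  est <- matrix(NA_real_, n, length(p_names),
                dimnames = list(obs$record_id, p_names))
  failures <- character(0)
  for (i in seq_len(n)) {
    fit_i <- tryCatch({
      d <- build_design(obs[-i, , drop = FALSE], spec_jk, A = A)
      suppressMessages(gibbs_fit(d))
    }, error = function(e) conditionMessage(e))
    if (is.character(fit_i)) {
      failures[obs$record_id[i]] <- fit_i
    } else {
      est[i, ] <- colMeans(fit_i$beta)
    }
  }
  ok <- est[stats::complete.cases(est), , drop = FALSE]
  if (nrow(ok) < 2L) stop("too few successful jackknife refits",
                          call. = FALSE)
  m <- nrow(ok)
  theta_bar <- colMeans(ok)
  se <- sqrt((m - 1) / m * colSums(sweep(ok, 2, theta_bar)^2))
  structure(list(estimates = est, mean = theta_bar, se = se,
                 failures = failures),
            class = "fmr_jackknife")
}

#' @export
print.fmr_jackknife <- function(x, ...) {
  cat(sprintf("Jackknife over %d records (%d failed)\n",
              nrow(x$estimates), length(x$failures)))
  print(rbind(mean = x$mean, se = x$se))
  invisible(x)
}

#' DIC-based model selection
#'
#' Fits each candidate specification to the same data and tabulates DIC and
#' the difference from the best (lowest-DIC) model. Ties are broken by the
#' fewest fixed-effect terms — the simplest model with the lowest DIC is
#' considered the strongest. A candidate whose fit fails is excluded with
#' its reason; the comparison proceeds if at least two remain.
#'
#' @param specs list of at least two [model_spec()] candidates.
#' @param observations validated `fmr_data` table.
#' @param A optional `phylo_correlation`.
#' @return object of class `fmr_model_comparison`: data.frame with columns
#'   `model`, `n_fixed_terms`, `dic`, `delta_dic`, `best`, plus an
#'   `excluded` attribute naming failed candidates.
#' @export
model_selection <- function(specs, observations, A = NULL) {
  if (length(specs) < 2L) {
    stop("model_selection requires at least 2 candidate specs",
         call. = FALSE)
  }
  labels <- vapply(specs, function(s)
    paste(s$fixed_terms, collapse = "+"), character(1))
  rows <- list()
  excluded <- character(0)
  for (i in seq_along(specs)) {
    res <- tryCatch({
      d <- build_design(observations, specs[[i]], A = A)
      fit <- suppressMessages(gibbs_fit(d))
      compute_dic(fit)$dic
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded[labels[i]] <- res
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        model = labels[i],
        n_fixed_terms = length(specs[[i]]$fixed_terms),
        dic = res, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) < 2L) {
    stop("fewer than 2 candidates fitted successfully; reasons: ",
         paste(sprintf("%s: %s", names(excluded), excluded),
               collapse = "; "), call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta_dic <- tab$dic - min(tab$dic)
  # best: lowest DIC, tie-break fewest fixed terms, then first listed
  cand <- which(tab$delta_dic == 0)
  best_i <- cand[order(tab$n_fixed_terms[cand])][1L]
  tab$best <- seq_len(nrow(tab)) == best_i
  tab <- tab[order(tab$dic, tab$n_fixed_terms), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("fmr_model_comparison", "data.frame"),
            excluded = excluded)
}

#' Summarize a fitted model (publication-table layout)
#'
#' Per fixed effect: posterior mean, 95% HPD bounds and pMCMC; posterior
#' means of the variance components; phylogenetic heritability mean and
#' s.d. (when the phylogeny term is present); DIC (when the design bundle
#' is available); and the retained draw count.
#'
#' @param fit an `fmr_posterior`.
#' @param prob HPD mass for the interval columns.
#' @return object of class `fmr_fit_summary`.
#' @export
summarize_fit <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "fmr_posterior"))
  terms <- colnames(fit$beta)
  eff <- do.call(rbind, lapply(terms, function(tm) {
    d <- fit$beta[, tm]
    h <- hpd_interval(d, prob)
    data.frame(effect = tm, estimate = mean(d),
               lower_95 = h[["lower"]], upper_95 = h[["upper"]],
               p_mcmc = p_mcmc(d), stringsAsFactors = FALSE)
  }))
  vc <- colMeans(fit$sigma2)
  h2 <- if ("phylogeny" %in% colnames(fit$sigma2)) {
    h <- heritability(fit$sigma2)
    c(mean = h$mean, sd = h$sd)
  }
  dic <- if (!is.null(fit$design) && !is.null(fit$deviance)) {
    compute_dic(fit)
  }
  structure(list(effects = eff, variance_components = vc, h2 = h2,
                 dic = dic, n_draws = nrow(fit$beta),
                 log_base = fit$meta$log_base),
            class = "fmr_fit_summary")
}

#' @export
print.fmr_fit_summary <- function(x, digits = 3, ...) {
  cat("Posterior summary (log base",
      if (abs(x$log_base - 10) < 1e-12) "10" else format(x$log_base), ")\n")
  eff <- x$effects
  eff$estimate <- signif(eff$estimate, digits)
  eff$lower_95 <- signif(eff$lower_95, digits)
  eff$upper_95 <- signif(eff$upper_95, digits)
  eff$p_mcmc <- ifelse(eff$p_mcmc < 0.001, "<0.001",
                       signif(eff$p_mcmc, digits))
  print(eff, row.names = FALSE)
  cat("variance components:",
      paste(sprintf("%s=%.4g", names(x$variance_components),
                    x$variance_components), collapse = ", "), "\n")
  if (!is.null(x$h2)) {
    cat(sprintf("phylogenetic heritability H2: mean = %.3f; s.d. = %.3f\n",
                x$h2[["mean"]], x$h2[["sd"]]))
  }
  if (!is.null(x$dic)) {
    cat(sprintf("DIC = %.2f (pD = %.2f)\n", x$dic$dic, x$dic$pd))
  }
  cat("retained draws:", x$n_draws, "\n")
  invisible(x)
}

#' Write a fit summary to CSV
#'
#' The effect table (effect, posterior estimate, lower/upper 95% CI, pMCMC)
#' followed by a key-value block (variance components, H2 mean/sd, DIC,
#' retained draw count).
#'
#' @param summary an `fmr_fit_summary`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(summary, path) {
  stopifnot(inherits(summary, "fmr_fit_summary"))
  utils::write.table(summary$effects, path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  kv <- c(
    sprintf("sigma2_%s,%.10g", names(summary$variance_components),
            summary$variance_components),
    if (!is.null(summary$h2)) c(sprintf("H2_mean,%.10g", summary$h2[["mean"]]),
                                sprintf("H2_sd,%.10g", summary$h2[["sd"]])),
    if (!is.null(summary$dic)) c(sprintf("DIC,%.10g", summary$dic$dic),
                                 sprintf("pD,%.10g", summary$dic$pd)),
    sprintf("n_draws,%d", summary$n_draws),
    sprintf("log_base,%.10g", summary$log_base))
  cat(kv, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Write a model comparison to CSV
#'
#' @param comparison an `fmr_model_comparison`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_model_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "fmr_model_comparison"))
  write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}
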