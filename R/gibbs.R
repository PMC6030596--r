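#' Fit the phylogenetic mixed model by Gibbs sampling
#'
#' Runs a conjugate Gibbs sweep over the Gaussian mixed model for log FMR
#' with parameter-expanded priors on the random-effect variances. Each sweep
#' updates, in order: the fixed effects (joint Gaussian conditional); each
#' random-effect vector (Gaussian conditional, using the A-structured
#' precision for the phylogeny term) followed by its working expansion
#' scalar; each random-effect variance and the residual variance
#' (inverse-Gamma conditionals). The conditional deviance
#' `-2 log N(y | X beta + sum Z u, sigma2_resid I)` is recorded at every
#' retained draw. One RNG seed fully determines the output.
#'
#' A ridge of `1e-8` is added to the diagonal of the phylogenetic
#' correlation matrix before factorization (reported via `message()`).
#'
#' @param design an [build_design()] bundle.
#' @param spec optional [model_spec()] override; defaults to the spec stored
#'   in the design.
#' @return object of class `fmr_posterior`: retained draws of `beta`
#'   (matrix, named columns), `sigma2` (matrix; one column per random term
#'   plus `residual`), `deviance`, per-level random effects `u`, the
#'   `design`, and `meta` (spec, seed, log base, data fingerprint).
#' @export
gibbs_fit <- function(design, spec = design$spec) {
  stopifnot(inherits(design, "fmr_design"), inherits(spec, "model_spec"))
  chain <- spec$chain
  if (chain$retained < 1L) {
    stop("chain config error: retained draw count is 0", call. = FALSE)
  }
  pr <- spec$priors
  p <- ncol(design$X)

  terms_cpp <- lapply(design$terms, function(tk) {
    Ainv <- NULL
    if (!is.null(tk$A)) {
      Ar <- tk$A + diag(1e-8, nrow(tk$A))
      message("phylogeny term: ridge 1e-8 added to A before factorization")
      Ainv <- chol2inv(chol(Ar))
    }
    list(map = as.integer(tk$map), q = length(tk$labels), Ainv = Ainv)
  })

  if (!is.null(chain$seed)) set.seed(chain$seed)
  res <- gibbs_pmm_cpp(
    y = as.numeric(design$y), X = design$X, terms = unname(terms_cpp),
    beta_prior_var = rep(pr$fixed_effect_prior_var, p),
    re_scale = pr$re_scale, re_df = pr$re_df,
    exp_mean = pr$expansion_mean, exp_var = pr$expansion_var,
    resid_scale = pr$residual_scale, resid_df = pr$residual_df,
    resid_fixed = if (is.null(pr$residual_fixed)) -1 else pr$residual_fixed,
    n_iter = chain$n_iter, burn_in = chain$burn_in, thin = chain$thin)

  beta <- res$beta
  colnames(beta) <- colnames(design$X)
  sigma2 <- res$sigma2
  colnames(sigma2) <- c(names(design$terms), "residual")
  u <- res$u
  names(u) <- names(design$terms)
  for (nm in names(u)) colnames(u[[nm]]) <- design$terms[[nm]]$labels

  fmr_posterior(beta = beta, sigma2 = sigma2,
                deviance = as.numeric(res$deviance),
                u = u, design = design,
                meta = list(spec = spec, seed = chain$seed,
                            log_base = spec$log_base,
                            fingerprint = design$fingerprint,
                            retained = chain$retained))
}

#' Construct a posterior-samples object
#'
#' Low-level constructor, used by [gibbs_fit()] and available directly for
#' building a calculator from published coefficients (a posterior degenerate
#' at fixed values is valid).
#'
#' @param beta matrix of fixed-effect draws, one named column per term.
#' @param sigma2 matrix of variance-component draws (columns among
#'   `phylogeny`, `species`, `colony` plus `residual`); all entries must be
#'   strictly positive.
#' @param deviance optional numeric vector of per-draw conditional deviance.
#' @param u optional list of per-level random-effect draw matrices.
#' @param design optional `fmr_design` (needed for DIC).
#' @param meta list of metadata (at least `log_base`).
#' @return object of class `fmr_posterior`.
#' @export
fmr_posterior <- function(beta, sigma2, deviance = NULL, u = NULL,
                          design = NULL, meta = list(log_base = 10)) {
  beta <- as.matrix(beta)
  sigma2 <- as.matrix(sigma2)
  if (is.null(colnames(beta))) stop("beta draws must have named columns")
  nd <- nrow(beta)
  if (nrow(sigma2) != nd) stop("beta and sigma2 draw counts differ")
  if (any(sigma2 <= 0)) stop("all variance draws must be strictly positive")
  if (!is.null(deviance)) {
    if (length(deviance) != nd) stop("deviance draw count differs")
    if (any(!is.finite(deviance))) stop("non-finite deviance draws")
  }
  if (!is.null(u)) {
    for (nm in names(u)) {
      if (nrow(u[[nm]]) != nd) stop("random-effect draw count differs")
    }
  }
  if (is.null(meta$log_base)) meta$log_base <- 10
  structure(list(beta = beta, sigma2 = sigma2, deviance = deviance,
                 u = u, design = design, meta = meta),
            class = "fmr_posterior")
}

#' @export
print.fmr_posterior <- function(x, ...) {
  cat(sprintf("FMR posterior: %d retained draws\n", nrow(x$beta)))
  cat("  fixed effects: ", paste(colnames(x$beta), collapse = ", "), "\n")
  cat("  variance components: ", paste(colnames(x$sigma2), collapse = ", "),
      "\n")
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' Serialize posterior draws to a directory
#'
#' Writes `draws.csv` (one column per parameter, one row per retained draw;
#' fixed effects prefixed `beta.`, variance components `sigma2.`, random
#' effects `u.<term>.<level>`, plus `deviance`) and `meta.json` (model spec,
#' seed, log base, data fingerprint).
#'
#' @param fit an `fmr_posterior`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "fmr_posterior"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- as.data.frame(fit$beta)
  names(flat) <- paste0("beta.", colnames(fit$beta))
  s2 <- as.data.frame(fit$sigma2)
  names(s2) <- paste0("sigma2.", colnames(fit$sigma2))
  flat <- cbind(flat, s2)
  if (!is.null(fit$u)) {
    for (nm in names(fit$u)) {
      um <- as.data.frame(fit$u[[nm]])
      names(um) <- paste0("u.", nm, ".", colnames(fit$u[[nm]]))
      flat <- cbind(flat, um)
    }
  }
  if (!is.null(fit$deviance)) flat$deviance <- fit$deviance
  write.csv(flat, file.path(dir, "draws.csv"), row.names = FALSE)
  meta <- fit$meta
  meta$spec <- spec_to_list(meta$spec)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read posterior draws written by [write_posterior()]
#'
#' Reconstructs an `fmr_posterior` sufficient for prediction and posterior
#' summaries (the design bundle is not serialized, so DIC is unavailable on
#' a re-read fit).
#'
#' @param dir directory containing `draws.csv` and `meta.json`.
#' @return an `fmr_posterior`.
#' @export
read_posterior <- function(dir) {
  draws <- read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), names(draws), value = TRUE)
    m <- as.matrix(draws[, cols, drop = FALSE])
    colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
    m
  }
  beta <- pick("beta")
  sigma2 <- pick("sigma2")
  ucols <- grep("^u\\.", names(draws), value = TRUE)
  u <- NULL
  if (length(ucols)) {
    terms <- unique(sub("^u\\.([^.]+)\\..*$", "\\1", ucols))
    u <- lapply(terms, function(tm) {
      cols <- grep(paste0("^u\\.", tm, "\\."), names(draws), value = TRUE)
      m <- as.matrix(draws[, cols, drop = FALSE])
      colnames(m) <- sub(paste0("^u\\.", tm, "\\."), "", cols)
      m
    })
    names(u) <- terms
  }
  fmr_posterior(beta = beta, sigma2 = sigma2,
                deviance = draws$deviance, u = u, meta = meta)
}

# model_spec -> plain list for JSON serialization
spec_to_list <- function(spec) {
  if (is.null(spec)) return(NULL)
  list(fixed_terms = spec$fixed_terms, random_terms = spec$random_terms,
       priors = unclass(spec$priors), chain = unclass(spec$chain),
       log_base = spec$log_base)
}
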