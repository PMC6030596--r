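#' Prior specification for the phylogenetic mixed model
#'
#' Defaults follow common practice for parameter-expanded variance priors:
#' each random-effect variance has an inner inverse-Gamma prior (scale
#' `re_scale`, degrees of belief `re_df`) expanded by a working scalar with a
#' Gaussian prior (`expansion_mean`, `expansion_var`), which induces a
#' heavy-tailed, approximately half-t prior on the effect standard deviation.
#' Fixed effects get independent zero-mean Gaussian priors with large
#' variance (effectively flat). The residual variance has a weak
#' inverse-Gamma prior, or can be held fixed at a known value (used by the
#' closed-form oracle tests).
#'
#' @param residual_scale,residual_df inverse-Gamma prior scale V and degrees
#'   of belief nu for the residual variance (prior is IG(nu/2, nu*V/2)).
#' @param re_scale,re_df inner inverse-Gamma scale/df for each random-effect
#'   variance under parameter expansion.
#' @param expansion_mean,expansion_var Gaussian prior on the working scalar.
#' @param fixed_effect_prior_var prior variance of each fixed-effect
#'   coefficient.
#' @param residual_fixed if non-`NULL`, the residual variance is held fixed
#'   at this value instead of being sampled.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(residual_scale = 1, residual_df = 0.002,
                       re_scale = 1, re_df = 1,
                       expansion_mean = 0, expansion_var = 625,
                       fixed_effect_prior_var = 1e8,
                       residual_fixed = NULL) {
  stopifnot(residual_scale > 0, residual_df > 0, re_scale > 0, re_df > 0,
            expansion_var > 0, fixed_effect_prior_var > 0,
            is.null(residual_fixed) ||
              (is.numeric(residual_fixed) && residual_fixed > 0))
  structure(list(residual_scale = residual_scale, residual_df = residual_df,
                 re_scale = re_scale, re_df = re_df,
                 expansion_mean = expansion_mean,
                 expansion_var = expansion_var,
                 fixed_effect_prior_var = fixed_effect_prior_var,
                 residual_fixed = residual_fixed),
            class = "prior_spec")
}

#' MCMC chain schedule
#'
#' The compiled-analysis default mirrors the original study's schedule:
#' 260 000 iterations, burn-in 60 000, thinning interval 200, retaining
#' exactly `floor((n_iter - burn_in) / thin) = 1000` draws.
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded before any draw is retained.
#' @param thin thinning interval (every `thin`-th post-burn-in iteration is
#'   kept).
#' @param seed integer RNG seed; one seed fully determines the chain.
#' @return object of class `chain_config` with a `retained` field.
#' @export
chain_config <- function(n_iter = 260000, burn_in = 60000, thin = 200,
                         seed = NULL) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  retained <- floor((n_iter - burn_in) / thin)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = if (!is.null(seed)) as.integer(seed),
                 retained = as.integer(retained)),
            class = "chain_config")
}

#' Model specification for the phylogenetic mixed model
#'
#' @param fixed fixed-effect terms, a subset of
#'   `c("log_mass", "phase", "abs_latitude", "brood_size", "log_rpp")`.
#'   The intercept is always included.
#' @param random random-effect terms, a subset of
#'   `c("phylogeny", "species", "colony")`. The phylogeny term requires a
#'   [tree_to_correlation()] matrix at design time.
#' @param priors a [prior_spec()].
#' @param chain a [chain_config()].
#' @param log_base base of the log transforms (10 or `exp(1)`); recorded in
#'   all fit outputs.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(fixed = c("log_mass", "phase", "abs_latitude"),
                       random = c("phylogeny", "species", "colony"),
                       priors = prior_spec(), chain = chain_config(),
                       log_base = 10) {
  fixed <- setdiff(unique(as.character(fixed)), "intercept")
  bad <- setdiff(fixed, TERM_ORDER)
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  random <- unique(as.character(random))
  badr <- setdiff(random, RANDOM_TERMS)
  if (length(badr)) stop("unknown random term(s): ",
                         paste(badr, collapse = ", "), call. = FALSE)
  stopifnot(inherits(priors, "prior_spec"), inherits(chain, "chain_config"),
            is.numeric(log_base), log_base > 1)
  fixed <- c("intercept", TERM_ORDER[TERM_ORDER %in% fixed])
  random <- RANDOM_TERMS[RANDOM_TERMS %in% random]
  structure(list(fixed_terms = fixed, random_terms = random,
                 priors = priors, chain = chain, log_base = log_base),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Phylogenetic mixed model specification\n")
  cat("  fixed:  ", paste(x$fixed_terms, collapse = " + "), "\n")
  cat("  random: ", if (length(x$random_terms))
    paste(x$random_terms, collapse = " + ") else "(none)", "\n")
  cat(sprintf("  chain:   %d iterations, burn-in %d, thin %d (%d retained)\n",
              x$chain$n_iter, x$chain$burn_in, x$chain$thin,
              x$chain$retained))
  cat(sprintf("  log base: %s\n",
              if (abs(x$log_base - 10) < 1e-12) "10" else
                format(x$log_base)))
  invisible(x)
}

# Expand "phase" into its dummy columns; returns design column names.
expand_fixed_terms <- function(fixed_terms) {
  out <- character(0)
  for (tm in fixed_terms) {
    out <- c(out, if (tm == "phase") c("phase_incubation", "phase_creche")
             else tm)
  }
  out
}
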