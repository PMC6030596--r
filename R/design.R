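#' Build the mixed-model design bundle
#'
#' Assembles the response vector (log FMR), the fixed-effect design matrix
#' and the random-effect incidence structure from a validated observation
#' table and a model specification. The phylogeny and species terms share
#' the species grouping but have distinct effect vectors: one correlated by
#' the phylogenetic matrix `A`, one identity-correlated. `A` is subset to
#' the observed species and reordered to the design's species levels.
#'
#' @param observations a validated `fmr_data` table.
#' @param spec a [model_spec()].
#' @param A a [tree_to_correlation()] `phylo_correlation`; required when
#'   `"phylogeny"` is among the random terms.
#' @return object of class `fmr_design`: list with `y`, `X`, `terms` (per
#'   random term: `map` record-to-level index, `labels`, and `A` for the
#'   phylogeny term), `spec`, and `record_id`.
#' @export
build_design <- function(observations, spec, A = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  obs <- validate_fmr(as.data.frame(observations))
  preds <- derive_predictors(obs, spec$log_base, terms = spec$fixed_terms)
  y <- preds$log_fmr
  names(y) <- obs$record_id

  xcols <- expand_fixed_terms(spec$fixed_terms)
  n <- nrow(obs)
  X <- matrix(1, n, length(xcols), dimnames = list(obs$record_id, xcols))
  for (cn in setdiff(xcols, "intercept")) X[, cn] <- preds[[cn]]
  for (cn in setdiff(xcols, "intercept")) {
    if (var(X[, cn]) == 0) {
      stop("unidentifiable design: predictor column '", cn,
           "' is constant", call. = FALSE)
    }
  }

  skey <- species_key(obs$species)
  ckey <- species_key(obs$colony)
  terms <- list()
  if ("phylogeny" %in% spec$random_terms) {
    if (is.null(A)) {
      stop("the phylogeny random term requires a phylo_correlation matrix",
           call. = FALSE)
    }
    stopifnot(inherits(A, "phylo_correlation"))
    sp_levels <- unique(skey)
    missing_sp <- setdiff(sp_levels, species_key(A$tip_order))
    if (length(missing_sp)) {
      orig <- unique(normalize_species(obs$species)[skey %in% missing_sp])
      stop("species missing from phylogenetic correlation matrix: ",
           paste(orig, collapse = ", "), call. = FALSE)
    }
    Asub <- subset_correlation(A, sp_levels)
    terms$phylogeny <- list(map = match(skey, sp_levels),
                            labels = Asub$tip_order, A = Asub$A)
  }
  if ("species" %in% spec$random_terms) {
    sp_levels <- unique(skey)
    terms$species <- list(map = match(skey, sp_levels),
                          labels = unique(normalize_species(obs$species)),
                          A = NULL)
  }
  if ("colony" %in% spec$random_terms) {
    c_levels <- unique(ckey)
    terms$colony <- list(map = match(ckey, c_levels),
                         labels = normalize_species(
                           obs$colony[match(c_levels, ckey)]),
                         A = NULL)
  }

  structure(list(y = y, X = X, terms = terms, spec = spec,
                 record_id = obs$record_id,
                 fingerprint = design_fingerprint(y, X)),
            class = "fmr_design")
}

# Lightweight reproducibility fingerprint recorded in fit metadata/logs.
design_fingerprint <- function(y, X) {
  list(n_records = length(y), n_fixed = ncol(X),
       y_sum = signif(sum(y), 12), x_sum = signif(sum(X), 12))
}

#' @export
print.fmr_design <- function(x, ...) {
  cat(sprintf("FMR design bundle: %d records, %d fixed-effect columns\n",
              length(x$y), ncol(x$X)))
  for (nm in names(x$terms)) {
    cat(sprintf("  random '%s': %d levels%s\n", nm,
                length(x$terms[[nm]]$labels),
                if (!is.null(x$terms[[nm]]$A)) " (A-correlated)" else ""))
  }
  invisible(x)
}
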