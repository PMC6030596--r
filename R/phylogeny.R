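#' Read a rooted phylogeny from a newick file
#'
#' Parses a single newick tree, normalizes tip labels (whitespace to
#' underscore), and checks structural invariants: branch lengths must be
#' present and non-negative, and tip labels must be unique after
#' case-insensitive normalization. Trees without branch lengths are rejected
#' explicitly rather than silently assigned unit lengths.
#'
#' @param path path to a newick file containing one tree.
#' @return an [ape::read.tree()] `phylo` object with normalized tip labels.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick_text(txt)
}

# Shared parser for file and in-memory newick strings.
parse_newick_text <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("newick parse error: empty input", call. = FALSE)
  # cheap well-formedness scan so errors carry a character offset
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("newick parse error: unbalanced ')' at character %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf("newick parse error: %d unclosed '(' at character %d",
                 depth, nchar(txt)), call. = FALSE)
  }
  if (!endsWith(txt, ";")) {
    stop(sprintf("newick parse error: missing terminating ';' at character %d",
                 nchar(txt) + 1L), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || is.null(tree$tip.label)) {
    stop("newick parse error: input not parseable as a tree", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("newick error: tree has no branch lengths ",
         "(unit lengths are not assumed)", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("newick error: some branch lengths are missing", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("newick error: negative branch lengths", call. = FALSE)
  }
  tree$tip.label <- normalize_species(tree$tip.label)
  keys <- species_key(tree$tip.label)
  if (anyDuplicated(keys)) {
    stop("newick error: duplicate tip labels after normalization: ",
         paste(unique(tree$tip.label[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  tree
}

#' Prune a phylogeny to a set of species
#'
#' Drops all tips not in `keep`, collapsing the resulting degree-2 internal
#' nodes (their branch lengths are summed), so path lengths between retained
#' tips are unchanged. Matching is whitespace- and case-insensitive.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of species names to retain.
#' @return the pruned `phylo` object.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep_keys <- unique(species_key(keep))
  tip_keys <- species_key(tree$tip.label)
  unmatched <- setdiff(keep_keys, tip_keys)
  if (length(unmatched)) {
    orig <- unique(normalize_species(keep))[
      species_key(unique(normalize_species(keep))) %in% unmatched]
    stop("species absent from tree: ", paste(orig, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep_keys) < 2L) {
    stop("cannot prune to fewer than 2 tips", call. = FALSE)
  }
  ape::keep.tip(tree, tree$tip.label[tip_keys %in% keep_keys])
}

#' Phylogenetic correlation matrix from a tree
#'
#' Builds the Brownian-motion expected correlation matrix of tip values:
#' `A[i, j]` is the root-to-MRCA shared path length of tips `i` and `j`
#' divided by the maximum root-to-tip depth. For an ultrametric tree this is
#' the standard scaled phylogenetic covariance with unit diagonal. For a
#' non-ultrametric input the diagonal is forced to 1 after scaling
#' (equivalent to rescaling tip-specific terminal variance) and a warning
#' records the largest pre-adjustment deviation.
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @return object of class `phylo_correlation`: a list with `tip_order`
#'   (species labels) and `A` (the correlation matrix).
#' @export
tree_to_correlation <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  max_depth <- max(depths)
  if (max_depth <= 0) stop("zero-depth tree: all branch lengths are 0",
                           call. = FALSE)
  coph <- ape::cophenetic.phylo(tree)
  coph <- coph[tree$tip.label, tree$tip.label]
  shared <- (outer(depths, depths, "+") - coph) / 2
  A <- shared / max_depth
  dev <- max(abs(diag(A) - 1))
  if (dev > 1e-8) {
    warning(sprintf(
      "tree is not ultrametric: max |diag - 1| = %.3g before adjustment; diagonal forced to 1",
      dev), call. = FALSE)
  }
  diag(A) <- 1
  A[A < 0] <- 0
  A[A > 1] <- 1
  dimnames(A) <- list(tree$tip.label, tree$tip.label)
  structure(list(tip_order = tree$tip.label, A = A),
            class = "phylo_correlation")
}

#' @export
print.phylo_correlation <- function(x, ...) {
  cat(sprintf("Phylogenetic correlation matrix: %d species\n",
              length(x$tip_order)))
  invisible(x)
}

# Subset a phylo_correlation to a set of species keys (order of `keys`).
subset_correlation <- function(pc, keys) {
  tip_keys <- species_key(pc$tip_order)
  idx <- match(keys, tip_keys)
  if (anyNA(idx)) {
    stop("species missing from phylogenetic correlation matrix: ",
         paste(keys[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  structure(list(tip_order = pc$tip_order[idx],
                 A = pc$A[idx, idx, drop = FALSE]),
            class = "phylo_correlation")
}
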