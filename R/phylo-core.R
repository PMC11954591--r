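#' @importFrom stats optimize pt pchisq phyper p.adjust quantile rnorm rpois
#'   rbinom runif sd var setNames coef ks.test plogis qlogis complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Normalize species labels
#'
#' Genome-derived tables and phenotype registries frequently disagree on the
#' formatting of species names ("Mus musculus" vs "mus_musculus"). All
#' species matching inside the package happens after lower-casing and
#' converting spaces to underscores.
#'
#' @param x character vector of species labels.
#' @return normalized character vector.
#' @export
normalize_species <- function(x) {
  gsub(" ", "_", tolower(trimws(as.character(x))), fixed = TRUE)
}

#' Parse a newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] with the validation this package relies on: tip
#' labels must be unique (after normalization), every non-root edge must
#' carry a finite nonnegative length, and the tree should be ultrametric.
#' Ultrametricity is checked within a relative tolerance of the maximum
#' root-to-tip depth and produces a warning, not an error: published
#' time-calibrated trees are routinely off by rounding.
#'
#' @param text a newick string (used if `path` is `NULL`).
#' @param path optionally, a file to read the newick from instead.
#' @param ultra_tol relative ultrametricity tolerance (default 1e-6).
#' @return an object of class `phylo` (from ape) with normalized tip labels.
#' @export
parse_newick <- function(text = NULL, path = NULL, ultra_tol = 1e-6) {
  if (is.null(text) && is.null(path)) stop("provide `text` or `path`")
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string")
  open <- sum(strsplit(text, "")[[1]] == "(")
  close <- sum(strsplit(text, "")[[1]] == ")")
  if (open != close) {
    off <- which(cumsum((strsplit(text, "")[[1]] == "(") -
                        (strsplit(text, "")[[1]] == ")")) < 0)[1]
    stop(sprintf("malformed newick: unbalanced parentheses near character %d",
                 if (is.na(off)) nchar(text) else off))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop(sprintf(
                     "malformed newick near character 1: %s", conditionMessage(e))))
  if (is.null(tree)) stop("malformed newick: could not parse tree (character 1)")
  tree$tip.label <- normalize_species(tree$tip.label)
  validate_phylogeny(tree, ultra_tol = ultra_tol)
  tree
}

#' Validate a phylogeny against the package invariants
#'
#' @param tree a `phylo` object.
#' @param ultra_tol relative ultrametricity tolerance.
#' @return the tree, invisibly. Errors on duplicate tips or bad edge
#'   lengths; warns on non-ultrametric depth spread.
#' @export
validate_phylogeny <- function(tree, ultra_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("every edge must have a finite length >= 0")
  depths <- tip_depths(tree)
  spread <- diff(range(depths))
  if (spread > ultra_tol * max(depths))
    warning(sprintf(
      "tree is not ultrametric: root-to-tip depths span %.3g (max depth %.3g)",
      spread, max(depths)))
  invisible(tree)
}

#' Root-to-tip depths
#' @param tree a `phylo` object.
#' @return named numeric vector of root-to-tip path lengths, in tip order.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Serialize a phylogeny to newick
#' @param tree a `phylo` object.
#' @param path optional file to write to.
#' @return the newick string, invisibly if written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 15)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Brownian-motion covariance of a phylogeny
#'
#' Entry (i, j) is the shared path length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' This is the trait covariance (up to the rate sigma^2) implied by Brownian
#' motion along the tree, and the residual covariance of the PGLS model at
#' lambda = 1.
#'
#' @param tree a `phylo` object.
#' @param species optional subset/ordering of tip labels.
#' @return a symmetric matrix with dimnames set to the tip labels.
#' @export
bm_covariance <- function(tree, species = NULL) {
  V <- ape::vcv(tree)
  if (!is.null(species)) {
    species <- normalize_species(species)
    missing <- setdiff(species, rownames(V))
    if (length(missing))
      stop("species not in tree: ", paste(missing, collapse = ", "))
    V <- V[species, species, drop = FALSE]
  }
  V
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies every off-diagonal entry by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` returns the Brownian covariance; `lambda = 0`
#' removes all phylogenetic correlation.
#'
#' @param V a covariance matrix.
#' @param lambda scalar in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a scalar in [0, 1]")
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Simulate a continuous trait under Brownian motion
#'
#' Draws one realization of tip values from a multivariate normal with mean
#' `root_value` and covariance `sigma2 * bm_covariance(tree)`. Deterministic
#' for a fixed seed; the global RNG state is left untouched.
#'
#' @param tree a `phylo` object.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @param chol_V optional pre-computed upper Cholesky factor of
#'   `bm_covariance(tree)` (reused across many draws).
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed,
                        chol_V = NULL) {
  if (!is.numeric(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0")
  if (missing(seed)) stop("seed is required")
  if (is.null(chol_V)) chol_V <- chol(bm_covariance(tree))
  n <- ncol(chol_V)
  z <- withr::with_seed(as.integer(seed), rnorm(n))
  setNames(root_value + sqrt(sigma2) * drop(crossprod(chol_V, z)),
           colnames(chol_V))
}

#' Read / write per-tip value maps as two-column TSV (species, value)
#' @param path TSV file with a header row.
#' @return named numeric vector.
#' @export
read_tip_values <- function(path) {
  df <- read.delim(path)
  setNames(as.numeric(df[[2]]), normalize_species(df[[1]]))
}

#' @rdname read_tip_values
#' @param values named numeric vector.
#' @return `write_tip_values` returns `path` invisibly.
#' @export
write_tip_values <- function(values, path) {
  write.table(data.frame(species = names(values), value = unname(values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum-likelihood ancestral reconstruction of a continuous trait
#'
#' Under Brownian motion the ML estimates of internal-node states are the
#' GLS conditional expectations given the tips: with V the tip covariance,
#' mu the GLS root estimate, and c_k the covariance vector between node k
#' and the tips (root-to-MRCA path lengths),
#' `x_k = mu + c_k' V^{-1} (y - mu)`. The root estimate equals the GLS mean.
#'
#' @param tree a `phylo` object.
#' @param tip_values named numeric vector covering every tip.
#' @return numeric vector of estimates for internal nodes, named by ape node
#'   number (`ntip+1` is the root).
#' @export
reconstruct_ancestral <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  names(tip_values) <- normalize_species(names(tip_values))
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing tip value(s): ", paste(miss, collapse = ", "))
  y <- tip_values[tree$tip.label]
  V <- bm_covariance(tree)
  depths <- ape::node.depth.edgelength(tree)
  nnode <- tree$Nnode
  # covariance between internal node k and tip i: depth of MRCA(k, i)
  M <- ape::mrca(tree, full = TRUE)      # (ntip+nnode) square, node numbers
  internal <- (ntip + 1L):(ntip + nnode)
  Cnt <- matrix(depths[M[internal, seq_len(ntip), drop = FALSE]],
                nrow = nnode)
  Vi_y <- solve(V, y)
  Vi_1 <- solve(V, rep(1, ntip))
  mu <- sum(Vi_y) / sum(Vi_1)
  est <- mu + drop(Cnt %*% (Vi_y - mu * Vi_1))
  setNames(est, internal)
}
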