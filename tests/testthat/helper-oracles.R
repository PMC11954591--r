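# Independent oracles used across the suite. Everything here is written
# from the definitions, deliberately not sharing code paths with the
# package internals it checks.

rtree_seeded <- function(n, seed, ultrametric = FALSE) {
  withr::with_seed(seed, {
    if (ultrametric) ape::rcoal(n) else ape::rtree(n)
  })
}

# Naive path-walk covariance: shared branch length of the two root-to-tip
# paths, obtained by intersecting edge sets.
vcv_oracle <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_vertices <- function(v) {
    out <- integer(0)
    while (v != root) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  paths <- lapply(seq_len(nt), path_vertices)
  V <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt))
    for (j in seq_len(nt))
      V[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  V
}

# Shared path length between arbitrary vertices (tips or internal nodes),
# for the joint-GLS ancestral-state oracle.
vertex_cov_oracle <- function(tree, a, b) {
  root <- length(tree$tip.label) + 1L
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path <- function(v) {
    out <- integer(0)
    while (v != root) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  sum(elen[intersect(path(a), path(b))])
}

# Explicit normal-equations GLS.
gls_oracle <- function(y, X, C) {
  Ci <- solve(C)
  A <- t(X) %*% Ci %*% X
  beta <- solve(A, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  s2 <- drop(t(r) %*% Ci %*% r) / (n - p)
  list(beta = drop(beta), se = sqrt(s2 * diag(solve(A))), sigma2 = s2)
}

# Definitional BH step-up: sort, scale by m/i, cumulative min from the top,
# unsort, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(1, adj)[order(o)]
}

# Brute-force Hommel via closed testing with Simes local tests.
simes_p <- function(p) {
  p <- sort(p)
  min(length(p) * p / seq_along(p))
}
hommel_oracle <- function(p) {
  m <- length(p)
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
  vapply(seq_len(m), function(i) {
    vals <- vapply(Filter(function(s) i %in% s, subsets),
                   function(s) simes_p(p[s]), numeric(1))
    min(1, max(vals))
  }, numeric(1))
}

# Brute-force classic enrichment score from the running-sum definition:
# explicit walk over the list, positive deviation preferred on ties (with a
# tolerance for accumulation round-off).
es_oracle <- function(hit_mask) {
  N <- length(hit_mask)
  Nh <- sum(hit_mask)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit_mask[i]) 1 / Nh else -1 / (N - Nh)
    run[i] <- acc
  }
  mx <- max(run)
  mn <- min(run)
  if (mx >= -mn - 1e-9) mx else mn
}

# A small complete synthetic world reused by several files.
small_world <- function(seed = 42, n_species = 40, n_orthogroups = 120,
                        planted = list()) {
  simulate_dataset(sim_config(n_species = n_species,
                              n_orthogroups = n_orthogroups,
                              planted = planted, seed = seed))
}
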