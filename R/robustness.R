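new_null_distribution <- function(replicate_pvalues, observed_p, n_reps,
                                  seed, kind) {
  stopifnot(length(replicate_pvalues) == n_reps)
  structure(list(replicate_pvalues = replicate_pvalues,
                 observed_p = observed_p, n_reps = n_reps, seed = seed,
                 kind = kind),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution (%s): %d replicates, observed p = %s, empirical p = %.4g\n",
              x$kind, x$n_reps,
              if (is.na(x$observed_p)) "NA" else format(x$observed_p, digits = 3),
              if (is.na(x$observed_p)) NA_real_ else empirical_p(x)))
  invisible(x)
}

#' Variance-matched random gene-set null
#'
#' Robustness check for one gene set of interest: builds `n_reps` random
#' sets of the same size by sampling, for each target orthogroup, a
#' replacement orthogroup whose cross-species copy-number variance falls in
#' the same variance decile (deciles computed over all orthogroups of the
#' filtered matrix; target orthogroups are excluded from the candidate
#' pool, and sampling is without replacement within a replicate). Each
#' random set's aggregate count is run through the same gene-set PGLS as
#' the target, and the copy-number term's p-value is recorded. Within the
#' matched decile, sampling prefers candidates within a 30% log-variance window of the target (falling back to the 5 nearest in
#' log-variance): the variance distribution is long-tailed, and plain
#' decile sampling would systematically over-draw the extreme tail. An
#' empty decile falls back to the adjacent deciles with a warning.
#'
#' @param target_set character vector of target orthogroup ids.
#' @param M a filtered `cn_matrix`.
#' @param phenotypes a `phenotype_table`.
#' @param tree a `phylo` object.
#' @param covariate per-species covariate for the gene-set model.
#' @param phenotype_name phenotype screened (default `malignancy_rate`).
#' @param n_reps number of random sets (default 1000).
#' @param seed integer seed (mandatory).
#' @return a `null_distribution` of kind `variance_matched_sets`, with
#'   `observed_p` the target set's own p-value, plus attribute
#'   `replicate_sets` (list of sampled ids).
#' @export
variance_matched_set_null <- function(target_set, M, phenotypes, tree,
                                      covariate,
                                      phenotype_name = "malignancy_rate",
                                      n_reps = 1000, seed) {
  stopifnot(inherits(M, "cn_matrix"))
  if (missing(seed)) stop("seed is required")
  target_set <- unique(target_set)
  miss <- setdiff(target_set, M$orthogroups)
  if (length(miss)) stop("target orthogroups absent: ", paste(miss, collapse = ", "))
  pool <- setdiff(M$orthogroups, target_set)
  if (length(pool) < 10 * length(target_set))
    stop("candidate pool smaller than 10x the set size")
  v <- apply(M$counts, 1, var)
  breaks <- unique(quantile(v, probs = seq(0, 1, 0.1), names = FALSE))
  dec <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  names(dec) <- M$orthogroups
  ndec <- length(breaks) - 1L
  pool_by_dec <- split(pool, dec[pool])
  ctx <- .screen_context(phenotypes, phenotype_name, tree, covariate,
                         include_paired = NULL)
  run_set <- function(ids) {
    agg <- colSums(M$counts[ids, , drop = FALSE])
    .screen_one(ctx, agg, "set", phenotype_name)$p
  }
  observed_p <- run_set(target_set)
  warned <- FALSE
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(rep) {
      taken <- character(0)
      picked <- character(length(target_set))
      for (k in seq_along(target_set)) {
        d0 <- dec[[target_set[k]]]
        width <- 0L
        repeat {
          cand <- unlist(pool_by_dec[as.character(
            max(1L, d0 - width):min(ndec, d0 + width))], use.names = FALSE)
          cand <- setdiff(cand, taken)
          if (length(cand)) break
          if (d0 - width <= 1L && d0 + width >= ndec)
            stop("no candidate orthogroups left in any decile")
          width <- width + 1L
        }
        if (width > 0L && !warned) {
          warning("empty variance decile; widened to adjacent deciles")
          warned <<- TRUE
        }
        dlv <- abs(log1p(v[cand]) - log1p(v[[target_set[k]]]))
        close_by <- cand[dlv <= log(1.3)]
        cand <- if (length(close_by)) close_by
                else cand[order(dlv)[seq_len(min(5L, length(cand)))]]
        picked[k] <- cand[sample.int(length(cand), 1L)]
        taken <- c(taken, picked[k])
      }
      picked
    })
  })
  pvals <- vapply(draws, run_set, numeric(1))
  out <- new_null_distribution(pvals, observed_p, n_reps, seed,
                               "variance_matched_sets")
  attr(out, "replicate_sets") <- draws
  attr(out, "variance_deciles") <- list(breaks = breaks, decile = dec)
  out
}

#' Brownian-motion phenotype null
#'
#' Robustness check holding the observed aggregate copy numbers fixed:
#' simulates `n_reps` random continuous phenotypes under Brownian motion
#' on the tree (rate scaled so tips have unit variance at the mean
#' root-to-tip depth; root 0 — PGLS p-values are scale invariant, so this
#' is cosmetic), refits the same weighted PGLS of phenotype on aggregate +
#' covariate for each, and records the aggregate term's p-value.
#'
#' @param aggregate named per-species aggregate counts.
#' @param tree a `phylo` object.
#' @param covariate named per-species covariate (or `NULL`).
#' @param weights named per-species positive weights (or `NULL`).
#' @param n_reps number of simulated phenotypes (default 1000).
#' @param seed integer seed (mandatory).
#' @param observed_phenotype optional named per-species response; when
#'   given, the same model is fit to it and its p recorded as `observed_p`.
#' @return a `null_distribution` of kind `bm_phenotype`.
#' @export
bm_phenotype_null <- function(aggregate, tree, covariate = NULL,
                              weights = NULL, n_reps = 1000, seed,
                              observed_phenotype = NULL) {
  if (missing(seed)) stop("seed is required")
  names(aggregate) <- normalize_species(names(aggregate))
  sp <- intersect(normalize_species(tree$tip.label), names(aggregate))
  if (!is.null(covariate)) {
    names(covariate) <- normalize_species(names(covariate))
    sp <- intersect(sp, names(covariate))
  }
  if (!is.null(weights)) {
    names(weights) <- normalize_species(names(weights))
    sp <- intersect(sp, names(weights)[is.finite(weights) & weights > 0])
  }
  sub <- ape::keep.tip(tree, sp)
  V <- bm_covariance(sub)
  sp <- rownames(V)
  sigma2 <- 1 / mean(diag(V))
  cV <- chol(V)
  structure <- pgls_structure(sub, sp,
                              if (is.null(weights)) NULL else weights[sp])
  preds <- c(list(aggregate = aggregate[sp]),
             if (is.null(covariate)) NULL else list(covariate = covariate[sp]))
  fit_p <- function(y) {
    des <- design_spec(y, preds,
                       weights = if (is.null(weights)) NULL else weights[sp])
    fit_pgls(des, structure = structure)$pvalues[["aggregate"]]
  }
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, n_reps))
  pvals <- vapply(seeds, function(s) {
    y <- simulate_bm(sub, sigma2 = sigma2, root_value = 0, seed = s,
                     chol_V = cV)
    fit_p(y[sp])
  }, numeric(1))
  observed_p <- NA_real_
  if (!is.null(observed_phenotype)) {
    names(observed_phenotype) <- normalize_species(names(observed_phenotype))
    observed_p <- fit_p(observed_phenotype[sp])
  }
  new_null_distribution(pvals, observed_p, n_reps, seed, "bm_phenotype")
}

#' Empirical p-value from a simulation null
#'
#' `(r + 1) / (n_reps + 1)` where `r` counts replicate p-values at or below
#' the observed one; the +1 convention avoids reporting zero.
#'
#' @param null a `null_distribution` with a non-missing `observed_p`.
#' @return scalar empirical p-value.
#' @export
empirical_p <- function(null) {
  stopifnot(inherits(null, "null_distribution"))
  if (is.na(null$observed_p)) stop("null has no observed p-value")
  r <- sum(null$replicate_pvalues <= null$observed_p)
  (r + 1) / (null$n_reps + 1)
}

#' Write a null distribution as TSV + JSON summary
#' @param null a `null_distribution`.
#' @param path output TSV of replicate p-values; `.json` summary sidecar.
#' @export
write_null <- function(null, path) {
  write.table(data.frame(replicate = seq_len(null$n_reps),
                         p = null$replicate_pvalues),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = null$kind, n_reps = null$n_reps, seed = null$seed,
         observed_p = null$observed_p,
         empirical_p = if (is.na(null$observed_p)) NULL else empirical_p(null)),
    paste0(sub("\\.tsv$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
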