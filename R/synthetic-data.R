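#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. Defaults mirror the
#' scale of a mammalian comparative study: 94 species, a unit-height
#' time-calibrated tree, copy numbers with tree-correlated variation and
#' strong across-orthogroup variance heterogeneity, and necropsy sample
#' sizes of tens of animals per species.
#'
#' @param n_species number of tips (>= 4).
#' @param n_orthogroups number of orthogroups.
#' @param lambda_true Pagel's lambda of the phenotype noise in \[0, 1\].
#' @param dispersion Brownian rate of the latent log copy-number process
#'   (> 0); larger values give both more tree correlation and more
#'   cross-species spread.
#' @param base_meanlog,base_sdlog log-normal parameters of per-orthogroup
#'   base copy number; `base_sdlog = 1` spreads per-orthogroup variances
#'   over several orders of magnitude.
#' @param annotated_frac fraction of orthogroups carrying a reference-gene
#'   symbol.
#' @param necropsy_range integer range (min, max) of necropsies/species.
#' @param planted list of planted effects, each a list with `name`,
#'   `size` (orthogroups in the set), `slope` (per aggregate-count unit,
#'   applied on the latent scale of the target phenotype) and `phenotype`
#'   (one of the screen phenotype names).
#' @param seed integer seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 94, n_orthogroups = 1000,
                       lambda_true = 1, dispersion = 0.3,
                       base_meanlog = log(3), base_sdlog = 1,
                       annotated_frac = 0.8, necropsy_range = c(20, 80),
                       planted = list(), seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_species >= 4, n_orthogroups >= 1, dispersion > 0,
            lambda_true >= 0, lambda_true <= 1,
            annotated_frac >= 0, annotated_frac <= 1,
            length(necropsy_range) == 2, necropsy_range[1] >= 1)
  for (pl in planted)
    stopifnot(is.character(pl$name), pl$size >= 1, is.finite(pl$slope),
              is.character(pl$phenotype))
  structure(list(n_species = n_species, n_orthogroups = n_orthogroups,
                 lambda_true = lambda_true, dispersion = dispersion,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 annotated_frac = annotated_frac,
                 necropsy_range = as.integer(necropsy_range),
                 planted = planted, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth species tree of unit height
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an ultrametric `phylo` with tips `sp001`, `sp002`, ... and all
#'   root-to-tip depths equal to 1.
#' @export
generate_tree <- function(n_species, seed) {
  stopifnot(n_species >= 2)
  if (missing(seed)) stop("seed is required")
  tree <- withr::with_seed(as.integer(seed),
                           ape::rphylo(n_species, birth = 1, death = 0))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  validate_phylogeny(tree)
  tree
}

#' Simulate a tree-correlated copy-number matrix
#'
#' Each orthogroup gets a base copy number drawn from a long-tailed
#' log-normal, a latent log-abundance evolving as Brownian motion on the
#' tree (rate = `dispersion`), and integer counts drawn as Poisson around
#' the exponentiated latent. This yields the three structures the
#' downstream tests rely on: integer counts, phylogenetic correlation, and
#' strong variance heterogeneity across orthogroups (needed for
#' variance-decile matching). A fraction of orthogroups is annotated with
#' synthetic reference symbols `g0001`, `g0002`, ...
#'
#' @param tree a `phylo` object.
#' @param n_orthogroups number of orthogroups.
#' @param dispersion latent Brownian rate (> 0).
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog base-abundance log-normal parameters.
#' @param annotated_frac fraction of orthogroups annotated.
#' @return a `cn_matrix`.
#' @export
simulate_copy_numbers <- function(tree, n_orthogroups, dispersion = 0.3,
                                  seed, base_meanlog = log(3),
                                  base_sdlog = 1, annotated_frac = 0.8) {
  stopifnot(dispersion > 0)
  if (missing(seed)) stop("seed is required")
  V <- bm_covariance(tree)
  cV <- chol(V)
  n <- ncol(V)
  counts <- withr::with_seed(as.integer(seed), {
    base <- exp(rnorm(n_orthogroups, base_meanlog, base_sdlog))
    out <- matrix(0L, n_orthogroups, n)
    for (g in seq_len(n_orthogroups)) {
      latent <- log(base[g]) +
        sqrt(dispersion) * drop(crossprod(cV, rnorm(n)))
      out[g, ] <- rpois(n, exp(latent))
    }
    out
  })
  dimnames(counts) <- list(sprintf("OG%04d", seq_len(n_orthogroups)),
                           colnames(V))
  n_ann <- round(annotated_frac * n_orthogroups)
  ann_idx <- withr::with_seed(as.integer(seed) + 1L,
                              sort(sample.int(n_orthogroups, n_ann)))
  annotation <- setNames(
    lapply(seq_len(n_ann), function(i) sprintf("g%04d", i)),
    rownames(counts)[ann_idx])
  cn_matrix(counts, annotation)
}

#' Simulate phenotypes with known planted effects
#'
#' Continuous traits are lambda-structured Brownian noise on the tree plus
#' the planted linear effects of (centred) aggregate set counts. Log body
#' size and log longevity are generated positively correlated (an
#' allometric slope on shared Brownian variation). Cancer phenotypes pass
#' a latent Gaussian through a logistic link to per-species neoplasia
#' prevalence and malignancy rate; counts are then sampled hierarchically:
#' necropsies uniform over `necropsy_range`, neoplasms binomial in
#' necropsies, malignant cases binomial in neoplasms.
#'
#' @param tree a `phylo` object.
#' @param config a `sim_config` (its `planted`, `lambda_true`,
#'   `necropsy_range` and `seed` fields are used).
#' @param aggregates named list of per-species aggregate counts for each
#'   planted set (may be empty when nothing is planted).
#' @return a `phenotype_table`.
#' @export
simulate_phenotypes <- function(tree, config, aggregates = list()) {
  stopifnot(inherits(config, "sim_config"))
  V <- bm_covariance(tree)
  sp <- rownames(V)
  n <- length(sp)
  Cl <- lambda_transform(V, config$lambda_true)
  cL <- chol(Cl)
  planted_term <- function(pheno) {
    out <- rep(0, n)
    for (pl in config$planted) {
      if (!identical(pl$phenotype, pheno)) next
      agg <- aggregates[[pl$name]]
      if (is.null(agg)) stop("no aggregate supplied for planted set ", pl$name)
      names(agg) <- normalize_species(names(agg))
      out <- out + pl$slope * (agg[sp] - mean(agg[sp]))
    }
    out
  }
  withr::with_seed(config$seed + 7L, {
    draw <- function() drop(crossprod(cL, rnorm(n)))
    x_bs <- draw(); x_lg <- draw(); x_np <- draw(); x_mr <- draw()
    log_bs <- log(5000) + 2.5 * x_bs + planted_term("body_size")
    log_lg <- log(180) + 0.25 * (log_bs - log(5000)) + 1.0 * x_lg +
      planted_term("longevity")
    prev_lat <- qlogis(0.30) + 0.8 * x_np + planted_term("neoplasia_prev")
    rate_lat <- qlogis(0.40) + 0.8 * x_mr + planted_term("malignancy_rate")
    n_nec <- sample(config$necropsy_range[1]:config$necropsy_range[2], n,
                    replace = TRUE)
    n_neo <- rbinom(n, n_nec, plogis(prev_lat))
    n_mal <- rbinom(n, n_neo, plogis(rate_lat))
    derive_cancer_phenotypes(data.frame(
      species = sp, body_size_g = exp(log_bs),
      longevity_months = exp(log_lg), n_necropsies = n_nec,
      n_neoplasia = n_neo, n_malignant = n_mal,
      stringsAsFactors = FALSE))
  })
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Convenience wrapper running the full generator: tree, copy-number
#' matrix, planted gene sets (disjoint draws from the annotated
#' orthogroups), their aggregates, and phenotypes. All randomness derives
#' from `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list with `tree`, `M` (`cn_matrix`), `sets` (`gene_sets`, may be
#'   absent if nothing planted), `mapping`, `aggregates`, `phenotypes`,
#'   `truth` (the planted definitions).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- generate_tree(config$n_species, seed = config$seed)
  M <- simulate_copy_numbers(tree, config$n_orthogroups,
                             dispersion = config$dispersion,
                             seed = config$seed + 1L,
                             base_meanlog = config$base_meanlog,
                             base_sdlog = config$base_sdlog,
                             annotated_frac = config$annotated_frac)
  annotated <- names(M$annotation)[lengths(M$annotation) > 0]
  # planted sets are meant to be testable and to carry a distributed signal:
  # restrict to orthogroups that survive the >50%-nonzero filter and whose
  # cross-species variance sits in the middle band (40th-60th percentile),
  # so no single member dominates the aggregate
  passes <- rownames(M$counts)[rowMeans(M$counts > 0) > 0.5]
  annotated <- intersect(annotated, passes)
  if (length(annotated) > 1) {
    v <- apply(M$counts[annotated, , drop = FALSE], 1, var)
    band <- quantile(v, c(0.4, 0.6), names = FALSE)
    mid <- annotated[v >= band[1] & v <= band[2]]
    if (length(mid)) annotated <- mid
  }
  mapping <- list()
  sets <- NULL
  if (length(config$planted)) {
    need <- sum(vapply(config$planted, function(pl) pl$size, numeric(1)))
    if (need > length(annotated))
      stop("not enough annotated orthogroups for the planted sets")
    picks <- withr::with_seed(config$seed + 2L,
                              sample(annotated, need))
    at <- 0L
    set_defs <- list()
    for (pl in config$planted) {
      ids <- picks[(at + 1L):(at + pl$size)]
      at <- at + pl$size
      mapping[[pl$name]] <- ids
      set_defs[[pl$name]] <- unlist(M$annotation[ids], use.names = FALSE)
    }
    sets <- gene_sets(set_defs, source_tag = "synthetic-planted")
  }
  aggregates <- lapply(mapping, function(ids)
    colSums(M$counts[ids, , drop = FALSE]))
  phenotypes <- simulate_phenotypes(tree, config, aggregates)
  list(tree = tree, M = M, sets = sets, mapping = mapping,
       aggregates = aggregates, phenotypes = phenotypes,
       truth = config$planted)
}

#' Write a simulated dataset to plain-text files
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir directory (created if needed).
#' @return the directory, invisibly. Writes `tree.nwk`, `counts.tsv`,
#'   `annotation.tsv`, `phenotypes.tsv`, `sets.gmt` (if any) and
#'   `truth.json`.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_newick(sim$tree, file.path(outdir, "tree.nwk"))
  write_counts(sim$M, file.path(outdir, "counts.tsv"))
  ann <- sim$M$annotation[lengths(sim$M$annotation) > 0]
  write.table(data.frame(orthogroup_id = names(ann),
                         symbols = vapply(ann, paste, "", collapse = ",")),
              file.path(outdir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$phenotypes[, c("species", "body_size_g",
                                 "longevity_months", "n_necropsies",
                                 "n_neoplasia", "n_malignant")],
              file.path(outdir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$sets)) write_gmt(sim$sets, file.path(outdir, "sets.gmt"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Packaged per-gene PGLS fixture for the TGF-beta-production gene set
#'
#' The published per-gene results (mouse-annotated gene, PGLS coefficient
#' of copy number on malignancy rate, standard error, t, p, adjusted p)
#' for the 12-gene "negative regulation of TGF-beta production" set: the
#' canonical example of individually nonsignificant genes whose shared
#' directionality drives a significant aggregate association.
#'
#' @return data.frame with columns `gene`, `estimate`, `se`, `t`, `p`,
#'   `p_adjusted` (12 rows).
#' @export
table1_fixture <- function() {
  data.frame(
    gene = c("Cd24a", "Cd2ap", "Cdh3", "Fbln1", "Fn1", "Furin", "Gata6",
             "Il13", "Laptm4b", "Met", "Tsku", "Tyrobp"),
    estimate = c(-0.046, -0.067, -0.058, -0.082, -0.011, -0.047, -0.033,
                 0.037, -0.015, -0.091, -0.049, -0.097),
    se = c(0.029, 0.032, 0.036, 0.035, 0.0049, 0.015, 0.014, 0.041, 0.043,
           0.025, 0.013, 0.041),
    t = c(-1.5, -2.0, -1.6, -2.3, -2.2, -3.0, -2.2, 0.89, -0.36, -3.6,
          -3.7, -2.3),
    p = c(0.11, 0.039, 0.11, 0.021, 0.025, 0.0034, 0.024, 0.37, 0.71,
          0.00041, 0.0003, 0.019),
    p_adjusted = c(0.55, 0.41, 0.54, 0.36, 0.36, 0.11, 0.21, 0.77, 0.97,
                   0.12, 0.063, 0.36),
    stringsAsFactors = FALSE)
}
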