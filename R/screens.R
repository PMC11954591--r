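# Model recipes for each phenotype: response transform, paired life-history
# covariate, and necropsy weighting. Body size and longevity enter models
# log-transformed; cancer phenotypes are proportions in [0, 1] and are
# weighted by sqrt(number of necropsies).
.phenotype_recipe <- function(phenotype_name) {
  switch(phenotype_name,
    body_size = list(response = function(ph) log(ph$body_size_g),
                     paired = function(ph) log(ph$longevity_months),
                     paired_name = "log_longevity", weighted = FALSE),
    longevity = list(response = function(ph) log(ph$longevity_months),
                     paired = function(ph) log(ph$body_size_g),
                     paired_name = "log_body_size", weighted = FALSE),
    neoplasia_prev = list(response = function(ph) ph$neoplasia_prevalence,
                          paired = NULL, weighted = TRUE),
    malignancy_prev = list(response = function(ph) ph$malignancy_prevalence,
                           paired = NULL, weighted = TRUE),
    malignancy_rate = list(response = function(ph) ph$malignancy_rate,
                           paired = NULL, weighted = TRUE),
    stop("unknown phenotype: ", phenotype_name)
  )
}

# Assemble response / covariates / weights for a screen. Returns NULL-free,
# species-aligned pieces plus the shared pgls_structure.
.screen_context <- function(phenotypes, phenotype_name, tree, covariate,
                            include_paired = NULL) {
  stopifnot(inherits(phenotypes, "data.frame"))
  rec <- .phenotype_recipe(phenotype_name)
  if (is.null(include_paired)) include_paired <- !is.null(rec$paired)
  sp <- normalize_species(phenotypes$species)
  y <- setNames(rec$response(phenotypes), sp)
  covs <- list(proteome = covariate[sp])
  if (include_paired && !is.null(rec$paired))
    covs[[rec$paired_name]] <- setNames(rec$paired(phenotypes), sp)
  w <- if (rec$weighted) setNames(phenotypes$weight, sp) else NULL
  keep <- is.finite(y)
  for (cv in covs) keep <- keep & is.finite(cv[sp])
  if (!is.null(w)) keep <- keep & is.finite(w) & w > 0
  sp <- intersect(sp[keep], normalize_species(tree$tip.label))
  y <- y[sp]
  covs <- lapply(covs, function(cv) cv[sp])
  w <- if (is.null(w)) setNames(rep(1, length(sp)), sp) else w[sp]
  structure <- pgls_structure(tree, sp, w)
  list(y = y, covs = covs, weights = w, species = sp, structure = structure)
}

# One PGLS of the context's response on `x` plus the context covariates.
# Returns the row for the screen table, or an untestable row on singular fit.
.screen_one <- function(ctx, x, unit_id, phenotype_name) {
  row <- data.frame(unit = unit_id, phenotype = phenotype_name,
                    estimate = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, lambda_hat = NA_real_,
                    n_species = length(ctx$species), testable = FALSE,
                    stringsAsFactors = FALSE)
  fit <- tryCatch({
    des <- design_spec(ctx$y, c(list(count = x[ctx$species]), ctx$covs),
                       weights = ctx$weights)
    if (!identical(des$species, ctx$species)) stop("species misalignment")
    fit_pgls(des, structure = ctx$structure)
  }, error = function(e) e)
  if (inherits(fit, "error")) return(row)
  row$estimate <- unname(fit$beta["count"])
  row$se <- unname(fit$se["count"])
  row$t <- unname(fit$tstats["count"])
  row$p <- unname(fit$pvalues["count"])
  row$lambda_hat <- fit$lambda_hat
  row$testable <- TRUE
  row
}

.finalize_screen <- function(rows, extra_adjust = FALSE) {
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- NA_real_
  ok <- tab$testable
  if (any(ok)) tab$p_adjusted[ok] <- adjust_pvalues(tab$p[ok], "BH")
  if (extra_adjust) {
    tab$p_bonferroni <- NA_real_
    tab$p_hommel <- NA_real_
    if (any(ok)) {
      tab$p_bonferroni[ok] <- adjust_pvalues(tab$p[ok], "bonferroni")
      tab$p_hommel[ok] <- adjust_pvalues(tab$p[ok], "hommel")
    }
  }
  tab <- tab[order(tab$p, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("screen_table", "data.frame")
  tab
}

#' Per-orthogroup PGLS screen of copy number against a phenotype
#'
#' Fits one weighted Pagel's-lambda PGLS per orthogroup: the phenotype is
#' the response; predictors are the orthogroup's copy number, a total
#' proteome-size covariate, and (for body size / longevity) the paired
#' life-history trait. Cancer phenotypes are weighted by
#' `sqrt(n_necropsies)`. P-values are Benjamini-Hochberg adjusted across
#' all testable orthogroups for the phenotype. Orthogroups producing a
#' singular design (e.g. constant copy number on the aligned species) are
#' retained with `testable = FALSE` and excluded from the BH family.
#'
#' @param M a `cn_matrix`, already passed through [filter_orthogroups()].
#' @param phenotypes a `phenotype_table`.
#' @param phenotype_name one of `body_size`, `longevity`, `neoplasia_prev`,
#'   `malignancy_prev`, `malignancy_rate`.
#' @param tree a `phylo` object.
#' @param covariate optional per-species proteome covariate; defaults to
#'   `proteome_covariate(M, "all")`.
#' @param include_paired override inclusion of the paired life-history
#'   covariate (default: included for body size and longevity only).
#' @return a `screen_table` data.frame sorted by ascending p.
#' @export
screen_orthogroups <- function(M, phenotypes, phenotype_name, tree,
                               covariate = NULL, include_paired = NULL) {
  stopifnot(inherits(M, "cn_matrix"))
  if (is.null(covariate)) covariate <- proteome_covariate(M, "all")
  ctx <- .screen_context(phenotypes, phenotype_name, tree, covariate,
                         include_paired)
  rows <- lapply(M$orthogroups, function(id)
    .screen_one(ctx, M$counts[id, ], id, phenotype_name))
  .finalize_screen(rows)
}

#' Aggregate gene-set PGLS screen
#'
#' Fits one weighted Pagel's-lambda PGLS per gene set, using the summed
#' copy number over the set's orthogroups as the single copy-number
#' predictor, with the reference-annotated proteome covariate (only
#' sequences attributable to a reference gene can enter a set). BH
#' adjustment across sets; Bonferroni and Hommel family-wise adjustments
#' are reported alongside.
#'
#' @param aggregates named list (or matrix set x species) of per-species
#'   aggregate counts per set.
#' @param phenotypes a `phenotype_table`.
#' @param phenotype_name as in [screen_orthogroups()].
#' @param tree a `phylo` object.
#' @param covariate per-species covariate, typically
#'   `proteome_covariate(M, "mouse_annotated")`.
#' @param include_paired see [screen_orthogroups()].
#' @return a `screen_table` with extra `p_bonferroni`, `p_hommel` columns.
#' @export
screen_gene_sets <- function(aggregates, phenotypes, phenotype_name, tree,
                             covariate, include_paired = NULL) {
  if (is.matrix(aggregates))
    aggregates <- setNames(lapply(seq_len(nrow(aggregates)), function(i)
      aggregates[i, ]), rownames(aggregates))
  ctx <- .screen_context(phenotypes, phenotype_name, tree, covariate,
                         include_paired)
  rows <- lapply(names(aggregates), function(nm)
    .screen_one(ctx, aggregates[[nm]], nm, phenotype_name))
  .finalize_screen(rows, extra_adjust = TRUE)
}

#' Multiple-testing adjustment
#'
#' Thin, validated wrapper over the standard step-up/step-down procedures:
#' Benjamini-Hochberg FDR, Bonferroni, and Hommel's closed-testing
#' procedure.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"`, `"bonferroni"` or `"hommel"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "hommel")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Reversed Poisson phylogenetic GLM check for significant gene sets
#'
#' For each supplied set, reverses the regression: the aggregate copy
#' number becomes the (Poisson) response and the malignancy rate the
#' predictor, with phylogenetic dependence as a GEE working correlation.
#' Confirms that trait-on-count associations survive when modelled on the
#' count scale.
#'
#' @param sets character vector of set names (e.g. the BH-significant rows
#'   of a [screen_gene_sets()] table), or a `screen_table` whose `unit`
#'   column is used.
#' @param aggregates named list of per-species aggregate counts.
#' @param phenotypes a `phenotype_table` (malignancy rate must be defined
#'   for included species).
#' @param tree a `phylo` object.
#' @param covariate optional per-species covariate added as predictor.
#' @param lambda working-correlation lambda (default 1).
#' @return data.frame with per-set estimate, se, z and p for the
#'   malignancy-rate term, sorted by p; empty input gives an empty table.
#' @export
reverse_pglm_check <- function(sets, aggregates, phenotypes, tree,
                               covariate = NULL, lambda = 1) {
  if (inherits(sets, "screen_table") || is.data.frame(sets)) sets <- sets$unit
  sets <- as.character(sets)
  empty <- data.frame(unit = character(), estimate = numeric(),
                      se = numeric(), z = numeric(), p = numeric(),
                      n_species = integer(), stringsAsFactors = FALSE)
  if (!length(sets)) return(empty)
  sp_all <- normalize_species(phenotypes$species)
  rate <- setNames(phenotypes$malignancy_rate, sp_all)
  rows <- lapply(sets, function(nm) {
    agg <- aggregates[[nm]]
    if (is.null(agg)) stop("no aggregate for set: ", nm)
    names(agg) <- normalize_species(names(agg))
    sp <- intersect(names(agg)[is.finite(agg)], sp_all[is.finite(rate[sp_all])])
    preds <- list(malignancy_rate = rate[sp])
    if (!is.null(covariate)) preds$covariate <- covariate[sp]
    fit <- fit_poisson_pglm(round(agg[sp]), preds, tree, lambda = lambda)
    data.frame(unit = nm,
               estimate = unname(fit$beta["malignancy_rate"]),
               se = unname(fit$se["malignancy_rate"]),
               z = unname(fit$tstats["malignancy_rate"]),
               p = unname(fit$pvalues["malignancy_rate"]),
               n_species = fit$n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$p), , drop = FALSE]
}

#' Count negative coefficients in a per-gene result table
#'
#' Summarizes directionality of a per-gene PGLS table (e.g. the packaged
#' TGF-beta-production set fixture): how many genes associate negatively
#' with the phenotype.
#'
#' @param fixture data.frame with an `estimate` column.
#' @return integer count of rows with `estimate < 0`.
#' @export
table1_directionality <- function(fixture) {
  if (!"estimate" %in% names(fixture)) stop("fixture needs an `estimate` column")
  sum(fixture$estimate < 0)
}

#' Write a screen table plus JSON sidecar
#' @param tab a `screen_table`.
#' @param path output TSV path; a `.json` sidecar with per-unit lambda and
#'   species counts is written next to it.
#' @export
write_screen <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(n_units = nrow(tab), n_testable = sum(tab$testable),
         phenotype = unique(tab$phenotype),
         lambda_hat = setNames(as.list(tab$lambda_hat), tab$unit)),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
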