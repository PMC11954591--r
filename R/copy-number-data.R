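#' Construct a validated copy-number matrix
#'
#' @param counts integer matrix, orthogroups in rows, species in columns.
#' @param annotation optional named list: orthogroup id -> character vector
#'   of reference-species (mouse) gene symbols; missing/empty entries mean
#'   "no annotation".
#' @return object of class `cn_matrix`: list with `counts` (matrix with
#'   dimnames), `orthogroups`, `species`, `annotation`.
#' @export
cn_matrix <- function(counts, annotation = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs orthogroup rownames and species colnames")
  colnames(counts) <- normalize_species(colnames(counts))
  if (anyDuplicated(rownames(counts))) stop("duplicate orthogroup ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate species")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at orthogroup '%s', species '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, , drop = FALSE]]))
  storage.mode(counts) <- "integer"
  ann <- vector("list", nrow(counts))
  names(ann) <- rownames(counts)
  if (!is.null(annotation)) {
    annotation <- annotation[intersect(names(annotation), rownames(counts))]
    for (id in names(annotation)) {
      sym <- annotation[[id]]
      sym <- sym[nzchar(sym)]
      if (length(sym)) ann[[id]] <- unique(sym)
    }
  }
  structure(list(counts = counts, orthogroups = rownames(counts),
                 species = colnames(counts), annotation = ann),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  n_ann <- sum(lengths(x$annotation) > 0)
  cat(sprintf("cn_matrix: %d orthogroups x %d species (%d annotated)\n",
              length(x$orthogroups), length(x$species), n_ann))
  invisible(x)
}

#' Read an orthogroup-by-species copy-number table
#'
#' TSV with a header row of species names; first column holds orthogroup
#' ids. Cells must be nonnegative integers.
#'
#' @param path TSV file.
#' @param annotation_path optional annotation TSV with columns
#'   `orthogroup_id` and comma-separated `symbols`.
#' @return a `cn_matrix`.
#' @export
read_counts <- function(path, annotation_path = NULL) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs an id column plus species columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate orthogroup ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) & m != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at orthogroup '%s', species '%s': '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]]))
  ann <- if (!is.null(annotation_path)) read_annotation(annotation_path) else NULL
  cn_matrix(num, ann)
}

#' Write a copy-number matrix as TSV
#' @param M a `cn_matrix`.
#' @param path output file.
#' @param id_col name of the id column (default "orthogroup_id").
#' @export
write_counts <- function(M, path, id_col = "orthogroup_id") {
  df <- data.frame(id = M$orthogroups, M$counts, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an orthogroup annotation table
#' @param path TSV with columns orthogroup_id, symbols (comma-separated).
#' @return named list orthogroup id -> character vector of symbols.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (ncol(df) < 2) stop("annotation table needs two columns")
  out <- lapply(df[[2]], function(s) {
    sym <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    unique(sym[nzchar(sym)])
  })
  names(out) <- df[[1]]
  out[lengths(out) > 0]
}

#' Filter orthogroups by fraction of species with nonzero copies
#'
#' Keeps orthogroups where strictly more than `min_frac` of species have a
#' nonzero copy number ("more than 50%" is read literally: exactly half is
#' excluded). Zero counts cannot be distinguished from annotation dropout,
#' so widely absent orthogroups are untrustworthy.
#'
#' @param M a `cn_matrix`.
#' @param min_frac threshold fraction in \[0, 1).
#' @return filtered `cn_matrix`.
#' @export
filter_orthogroups <- function(M, min_frac = 0.5) {
  stopifnot(inherits(M, "cn_matrix"))
  if (min_frac < 0 || min_frac >= 1) stop("min_frac must be in [0, 1)")
  frac <- rowMeans(M$counts > 0)
  keep <- frac > min_frac
  cn_matrix(M$counts[keep, , drop = FALSE],
            M$annotation[keep & lengths(M$annotation) > 0])
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description` (ignored; MSigDB puts a URL there), then member symbols.
#' Duplicate members within a set are deduplicated.
#'
#' @param path GMT file.
#' @param source_tag optional provenance label stored on the result.
#' @return object of class `gene_sets`: named list of character vectors,
#'   attribute `source`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", i))
    members <- unique(trimws(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT format error at line %d: empty set '%s'", i, f[1]))
    sets[[f[1]]] <- members
  }
  gene_sets(sets, source_tag)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors of gene symbols.
#' @param source_tag provenance label.
#' @return a `gene_sets` object.
#' @export
gene_sets <- function(sets, source_tag = "user") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every set needs a name")
  sets <- lapply(sets, function(s) unique(as.character(s[nzchar(s)])))
  if (any(lengths(sets) == 0)) stop("empty gene set")
  structure(sets, class = "gene_sets", source = source_tag)
}

#' Write gene sets as GMT
#' @param sets a `gene_sets`.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map gene sets onto orthogroups via reference-gene annotation
#'
#' An orthogroup belongs to a set iff any of its annotated reference-gene
#' symbols is a member of the set. Matching is case-insensitive (mouse
#' symbol capitalization is inconsistent across sources). Sets mapping to
#' zero orthogroups are dropped with a warning.
#'
#' @param sets a `gene_sets`.
#' @param M a `cn_matrix` with annotation.
#' @return named list: set name -> character vector of orthogroup ids.
#' @export
map_sets_to_orthogroups <- function(sets, M) {
  stopifnot(inherits(M, "cn_matrix"))
  ann <- M$annotation[lengths(M$annotation) > 0]
  if (!length(ann)) stop("no annotated orthogroups in matrix")
  og_ids <- rep(names(ann), lengths(ann))
  og_sym <- tolower(unlist(ann, use.names = FALSE))
  mapping <- lapply(sets, function(members) {
    unique(og_ids[og_sym %in% tolower(members)])
  })
  empty <- lengths(mapping) == 0
  if (any(empty)) {
    warning("dropping set(s) with no mapped orthogroups: ",
            paste(names(mapping)[empty], collapse = ", "))
    mapping <- mapping[!empty]
  }
  mapping
}

#' Aggregate copy number of a gene set per species
#'
#' Sums copy numbers over the orthogroups mapped to a set, each orthogroup
#' counted once even if several of its symbols belong to the set.
#'
#' @param M a `cn_matrix`.
#' @param mapping output of [map_sets_to_orthogroups()].
#' @param set_name name of the set.
#' @return named numeric vector of per-species aggregate counts.
#' @export
aggregate_set_counts <- function(M, mapping, set_name) {
  stopifnot(inherits(M, "cn_matrix"))
  if (!set_name %in% names(mapping)) stop("set has no mapping: ", set_name)
  ids <- unique(mapping[[set_name]])
  if (!length(ids)) stop("empty mapping for set: ", set_name)
  miss <- setdiff(ids, M$orthogroups)
  if (length(miss)) stop("mapped orthogroups absent from matrix: ",
                         paste(miss, collapse = ", "))
  colSums(M$counts[ids, , drop = FALSE])
}

#' Derive cancer phenotypes from necropsy counts
#'
#' From per-species totals of necropsies, observed neoplasms and malignant
#' neoplasms, derives: neoplasia prevalence (neoplasms per necropsy),
#' malignancy prevalence (malignant cases per necropsy), malignancy rate
#' (proportion of neoplasms diagnosed malignant), and the regression weight
#' `sqrt(n_necropsies)` used to downweight species whose prevalence rests
#' on few examined animals. Species with zero recorded neoplasms get a
#' missing malignancy rate and drop out of rate models.
#'
#' @param raw data.frame with columns `species`, `n_necropsies`,
#'   `n_neoplasia`, `n_malignant`, and optionally `body_size_g`,
#'   `longevity_months`.
#' @return data.frame of class `phenotype_table` with derived columns.
#' @export
derive_cancer_phenotypes <- function(raw) {
  req <- c("species", "n_necropsies", "n_neoplasia", "n_malignant")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- as.data.frame(raw)
  out$species <- normalize_species(out$species)
  if (anyDuplicated(out$species)) stop("duplicate species in phenotype table")
  with(out, {
    if (any(n_malignant > n_neoplasia))
      stop("n_malignant exceeds n_neoplasia for: ",
           paste(species[n_malignant > n_neoplasia], collapse = ", "))
    if (any(n_neoplasia > n_necropsies))
      stop("n_neoplasia exceeds n_necropsies for: ",
           paste(species[n_neoplasia > n_necropsies], collapse = ", "))
  })
  out$neoplasia_prevalence <- out$n_neoplasia / out$n_necropsies
  out$malignancy_prevalence <- out$n_malignant / out$n_necropsies
  out$malignancy_rate <- ifelse(out$n_neoplasia > 0,
                                out$n_malignant / out$n_neoplasia, NA_real_)
  out$weight <- sqrt(out$n_necropsies)
  rownames(out) <- out$species
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read a phenotype TSV and derive cancer phenotypes
#' @param path TSV with columns species, body_size_g, longevity_months,
#'   n_necropsies, n_neoplasia, n_malignant.
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  derive_cancer_phenotypes(read.delim(path))
}

#' Proteome-size covariate from a copy-number matrix
#'
#' Per-species totals used to absorb annotation-depth bias: `mode = "all"`
#' sums every orthogroup (proxy for proteome size, used in per-orthogroup
#' screens); `mode = "mouse_annotated"` restricts to orthogroups carrying a
#' reference-gene annotation (used in gene-set screens, whose sets are
#' defined by reference symbols).
#'
#' @param M a `cn_matrix`.
#' @param mode `"all"` or `"mouse_annotated"`.
#' @return named numeric vector per species.
#' @export
proteome_covariate <- function(M, mode = c("all", "mouse_annotated")) {
  stopifnot(inherits(M, "cn_matrix"))
  mode <- match.arg(mode)
  if (mode == "all") return(colSums(M$counts))
  keep <- lengths(M$annotation) > 0
  if (!any(keep)) {
    warning("no annotated orthogroups; mouse_annotated covariate is all zero")
    return(setNames(rep(0, length(M$species)), M$species))
  }
  colSums(M$counts[keep, , drop = FALSE])
}
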