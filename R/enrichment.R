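#' Build a ranked gene list from screen results
#'
#' Formalizes the two-group-then-rank recipe as a single signed score:
#' genes whose copy number associates positively with the phenotype get
#' score `-log10(p)`, negatively associated genes get `log10(p)`; sorting
#' by descending score puts the strongest positive associations at the top
#' and the strongest negative associations at the bottom. Ties are broken
#' by `|estimate|` (descending), then symbol. Orthogroups are expanded to
#' their annotated reference symbols; a symbol appearing for several
#' orthogroups keeps its smallest-p occurrence.
#'
#' @param screen a `screen_table` from [screen_orthogroups()].
#' @param annotation named list orthogroup id -> symbols (e.g.
#'   `M$annotation`).
#' @return data.frame of class `ranked_list` with columns `symbol`,
#'   `score`, `estimate`, `p`, sorted by descending score.
#' @export
build_ranked_list <- function(screen, annotation) {
  stopifnot(is.data.frame(screen))
  ok <- screen$testable & is.finite(screen$p) & is.finite(screen$estimate)
  screen <- screen[ok, , drop = FALSE]
  ann <- annotation[lengths(annotation) > 0]
  idx <- match(screen$unit, names(ann))
  keep <- !is.na(idx)
  screen <- screen[keep, , drop = FALSE]
  syms <- ann[idx[keep]]
  df <- data.frame(symbol = unlist(syms, use.names = FALSE),
                   estimate = rep(screen$estimate, lengths(syms)),
                   p = rep(screen$p, lengths(syms)),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no annotated, testable rows to rank")
  if (any(df$p == 0)) {
    warning("p-values of 0 replaced by smallest representable positive")
    df$p[df$p == 0] <- .Machine$double.xmin
  }
  # one entry per gene: keep the smallest-p occurrence
  df <- df[order(df$p), , drop = FALSE]
  df <- df[!duplicated(tolower(df$symbol)), , drop = FALSE]
  df$score <- sign(df$estimate) * -log10(df$p)
  ord <- order(-df$score, -abs(df$estimate), df$symbol)
  df <- df[ord, c("symbol", "score", "estimate", "p"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", "data.frame")
  df
}

# Classic (unweighted) enrichment score: running sum over the ranked list,
# +1/Nh at hits and -1/(N-Nh) at misses; ES is the extremum of largest
# magnitude (ties resolved toward the positive deviation).
.classic_es <- function(hit_mask) {
  N <- length(hit_mask)
  Nh <- sum(hit_mask)
  if (Nh == 0L || Nh == N) stop("set must hit some but not all of the list")
  steps <- ifelse(hit_mask, 1 / Nh, -1 / (N - Nh))
  run <- cumsum(steps)
  mx <- max(run)
  mn <- min(run)
  # exact ties between the positive and negative extremum resolve to the
  # positive deviation; the tolerance absorbs accumulation round-off
  if (mx >= -mn - 1e-12) mx else mn
}

#' Preranked GSEA with the classic (unweighted) statistic
#'
#' For each gene set, computes the classic enrichment score over the ranked
#' list (maximum signed deviation of the hit/miss running sum), assesses
#' significance by gene-label permutation (resampling which positions are
#' hits, `n_perm` times), normalizes ES by the mean of sign-matched
#' permutation ES values, and BH-adjusts p-values separately within the
#' positive and negative direction.
#'
#' @param ranked a `ranked_list` (or data.frame with `symbol` ordered).
#' @param sets a `gene_sets` collection.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (mandatory).
#' @return data.frame with columns `set`, `size`, `ES`, `NES`, `p`,
#'   `p_adjusted`, `direction`, sorted by p.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 10000, seed) {
  if (missing(seed)) stop("seed is required")
  symbols <- tolower(ranked$symbol)
  N <- length(symbols)
  sizes <- integer(0)
  rows <- list()
  perms_by_size <- new.env(parent = emptyenv())
  seeds <- withr::with_seed(as.integer(seed), sample.int(2^31 - 2, length(sets)))
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    hit_mask <- symbols %in% tolower(sets[[nm]])
    Nh <- sum(hit_mask)
    if (Nh == 0L) next
    if (Nh == N) stop("set '", nm, "' covers the whole ranked list")
    es <- .classic_es(hit_mask)
    perm_es <- withr::with_seed(seeds[i], vapply(seq_len(n_perm), function(b) {
      mask <- logical(N)
      mask[sample.int(N, Nh)] <- TRUE
      .classic_es(mask)
    }, numeric(1)))
    same_sign <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
    p <- (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, size = Nh, ES = es, NES = nes, p = p,
      direction = if (es >= 0) "positive" else "negative",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), p = numeric(), p_adjusted = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- NA_real_
  for (d in unique(tab$direction)) {
    idx <- tab$direction == d
    tab$p_adjusted[idx] <- adjust_pvalues(tab$p[idx], "BH")
  }
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, a one-sided hypergeometric upper-tail test of the
#' overlap between the significant genes and the set, relative to the
#' testable background (enrichment must be judged against what could have
#' been called significant, not the whole genome). BH adjustment across
#' sets; the `significant` flag applies FDR < 0.05.
#'
#' @param significant character vector of significant gene symbols
#'   (subset of `background`).
#' @param background character vector of all testable gene symbols.
#' @param sets a `gene_sets` collection.
#' @return data.frame with `set`, `set_size` (in background), `overlap`,
#'   `fold`, `p`, `p_adjusted`, `significant`, sorted by p.
#' @export
ora_test <- function(significant, background, sets) {
  background <- unique(tolower(background))
  significant <- unique(tolower(significant))
  if (!length(background)) stop("empty background")
  extra <- setdiff(significant, background)
  if (length(extra))
    stop("significant genes missing from background: ",
         paste(head(extra, 5), collapse = ", "))
  N <- length(background)
  n <- length(significant)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(tolower(sets[[nm]]), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, significant))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(set = nm, set_size = K, overlap = k, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), fold = numeric(), p = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- adjust_pvalues(tab$p, "BH")
  tab$significant <- tab$p_adjusted < 0.05
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
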