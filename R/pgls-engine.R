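#' Build a design specification for phylogenetic regression
#'
#' Aligns a response, predictor columns and observation weights on a common
#' species set and validates the result: no missing values after alignment
#' and a full-column-rank design (intercept added implicitly). Weights are
#' reliability weights: a species with weight w has its residual variance
#' scaled by 1/w, so only relative weights matter.
#'
#' @param response named numeric vector (names are species).
#' @param predictors data.frame or named list of named numeric vectors.
#' @param weights named numeric vector of positive weights, or `NULL` for
#'   unit weights.
#' @return an object of class `design_spec` with elements `y`, `X` (with
#'   intercept column), `weights`, `species`.
#' @export
design_spec <- function(response, predictors, weights = NULL) {
  resp_sp <- normalize_species(names(response))
  if (is.null(resp_sp) || anyDuplicated(resp_sp))
    stop("response must be named by unique species")
  names(response) <- resp_sp
  predictors <- as.data.frame(predictors, optional = TRUE)
  if (is.null(rownames(predictors)) ||
      identical(rownames(predictors), as.character(seq_len(nrow(predictors))))) {
    if (nrow(predictors) != length(response))
      stop("predictors have no species rownames and differ in length")
    rownames(predictors) <- resp_sp
  } else {
    rownames(predictors) <- normalize_species(rownames(predictors))
  }
  species <- intersect(resp_sp, rownames(predictors))
  if (!is.null(weights)) {
    names(weights) <- normalize_species(names(weights))
    species <- intersect(species, names(weights))
  }
  y <- response[species]
  X <- as.matrix(predictors[species, , drop = FALSE])
  keep <- is.finite(y) & apply(is.finite(X), 1, all)
  species <- species[keep]
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  w <- if (is.null(weights)) setNames(rep(1, length(species)), species)
       else weights[species]
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  if (length(species) == 0L) stop("no species left after alignment")
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(y = y, X = X, weights = w, species = species),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec: %d species, %d columns (%s)\n",
              length(x$species), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

# Cholesky with one jittered retry, then hard error.
chol_safe <- function(C) {
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out)) {
    jitter <- 1e-10 * sum(diag(C))
    out <- tryCatch(chol(C + diag(jitter, nrow(C))),
                    error = function(e) stop("covariance matrix is not positive definite"))
  }
  out
}

new_pgls_fit <- function(beta, se, lambda_hat, sigma2_hat, loglik, n, p,
                         method = "ML") {
  tstats <- beta / se
  pvalues <- 2 * pt(abs(tstats), df = n - p, lower.tail = FALSE)
  structure(list(beta = beta, se = se, lambda_hat = lambda_hat,
                 sigma2_hat = sigma2_hat, loglik = loglik, n = n, p = p,
                 tstats = tstats, pvalues = pvalues, method = method),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic GLS fit (%s): n = %d, lambda = %.4f, sigma2 = %.4g, logLik = %.3f\n",
              x$method, x$n, x$lambda_hat, x$sigma2_hat, x$loglik))
  tab <- data.frame(Estimate = x$beta, `Std.Error` = x$se, t = x$tstats,
                    p = x$pvalues, check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' Generalized least squares with a fixed covariance matrix
#'
#' Solves the weighted GLS problem for a given residual covariance `C`
#' (typically a lambda-transformed phylogenetic covariance). With weights w,
#' the working covariance is `diag(1/sqrt(w)) C diag(1/sqrt(w))`. Returns
#' `beta = (X'C^-1 X)^-1 X'C^-1 y`, standard errors from
#' `sigma2_hat (X'C^-1 X)^-1` with `sigma2_hat = r'C^-1 r / (n - p)`, and
#' the ML Gaussian log-likelihood (profiled sigma^2 = RSS/n).
#'
#' @param design a `design_spec`.
#' @param C residual covariance matrix aligned to `design$species` (species
#'   dimnames required unless dimensions already match in order).
#' @param lambda value recorded in the `lambda_hat` slot (bookkeeping only).
#' @return a `pgls_fit`.
#' @export
fit_gls <- function(design, C, lambda = NA_real_) {
  stopifnot(inherits(design, "design_spec"))
  sp <- design$species
  if (!is.null(dimnames(C)) && !is.null(rownames(C))) {
    rn <- normalize_species(rownames(C))
    if (!all(sp %in% rn)) stop("C lacks species: ",
                               paste(setdiff(sp, rn), collapse = ", "))
    dimnames(C) <- list(rn, rn)
    C <- C[sp, sp, drop = FALSE]
  } else if (nrow(C) != length(sp)) {
    stop("C has wrong dimensions and no species dimnames")
  }
  sw <- 1 / sqrt(design$weights)
  Cw <- C * tcrossprod(sw)
  n <- length(design$y)
  p <- ncol(design$X)
  if (n <= p) stop(sprintf("insufficient data: %d species for %d coefficients", n, p))
  L <- chol_safe(Cw)
  # whiten: solve L' z = v  =>  z = backsolve(L, v, transpose = TRUE)
  yt <- backsolve(L, design$y, transpose = TRUE)
  Xt <- backsolve(L, design$X, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- drop(solve(XtX, crossprod(Xt, yt)))
  names(beta) <- colnames(design$X)
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  sigma2_hat <- rss / (n - p)
  se <- sqrt(sigma2_hat * diag(solve(XtX)))
  names(se) <- names(beta)
  logdet <- 2 * sum(log(diag(L)))
  s2ml <- rss / n
  loglik <- -0.5 * (n * (log(2 * pi) + log(s2ml) + 1) + logdet)
  new_pgls_fit(beta, se, lambda, sigma2_hat, loglik, n, p)
}

#' Pre-computed spectral structure for fast repeated PGLS fits
#'
#' The weighted Pagel's-lambda covariance factorizes as
#' `C(lambda) = Wt^{1/2} (lambda K + (1-lambda) I) Wt^{1/2}`, where `Wt` is
#' the diagonal `diag(V)/w` and `K` the Brownian correlation matrix of the
#' tree (independent of the weights). One eigendecomposition of `K` then
#' makes every profile-likelihood evaluation O(n p); a screen over
#' thousands of orthogroups on a fixed tree and weight vector reuses it.
#'
#' @param tree a `phylo` object.
#' @param species species to include, in model order.
#' @param weights named positive weights (default unit).
#' @return a `pgls_structure` list used by [fit_pgls()].
#' @export
pgls_structure <- function(tree, species = NULL, weights = NULL) {
  V <- bm_covariance(tree, species)
  sp <- rownames(V)
  if (is.null(weights)) {
    w <- setNames(rep(1, length(sp)), sp)
  } else {
    names(weights) <- normalize_species(names(weights))
    if (!all(sp %in% names(weights)))
      stop("weights missing for: ", paste(setdiff(sp, names(weights)), collapse = ", "))
    w <- weights[sp]
    if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  }
  dV <- diag(V)
  K <- V / sqrt(tcrossprod(dV))          # BM correlation
  eig <- eigen(K, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  wt <- dV / w                           # diagonal of Wt
  structure(list(species = sp, Q = eig$vectors, evals = evals,
                 wt = wt, logdet_wt = sum(log(wt))),
            class = "pgls_structure")
}

# Profile log-likelihood pieces at a fixed lambda, on the rotated scale.
# u, U are Q' Wt^{-1/2} y and Q' Wt^{-1/2} X.
.gls_at_lambda <- function(lambda, u, U, evals, logdet_wt) {
  d <- lambda * evals + (1 - lambda)
  if (any(d <= 0)) return(list(loglik = -Inf))
  n <- length(u)
  Ud <- U / d
  XtX <- crossprod(U, Ud)
  Xty <- crossprod(Ud, u)
  beta <- drop(solve(XtX, Xty))
  r <- u - U %*% beta
  rss <- sum(r^2 / d)
  s2ml <- rss / n
  loglik <- -0.5 * (n * (log(2 * pi) + log(s2ml) + 1) + sum(log(d)) + logdet_wt)
  list(loglik = loglik, beta = beta, rss = rss, XtX = XtX, d = d)
}

#' Weighted PGLS with profiled Pagel's lambda
#'
#' Fits the phylogenetic regression `y = X beta + e`,
#' `e ~ N(0, sigma^2 D^{-1/2} V(lambda) D^{-1/2})` with `D = diag(weights)`
#' and `V(lambda)` the lambda-transformed Brownian covariance of the tree.
#' `lambda` is profiled by bounded ML over \[0, 1\] (tolerance 1e-6);
#' boundary values are reported when the boundary log-likelihood is at
#' least as high as the interior optimum.
#'
#' @param design a `design_spec`.
#' @param tree a `phylo` object (ignored when `structure` given).
#' @param structure optional [pgls_structure()] matching the design's
#'   species and weights.
#' @param lambda optional fixed lambda; skips profiling.
#' @return a `pgls_fit` with `lambda_hat` at the profile optimum.
#' @export
fit_pgls <- function(design, tree = NULL, structure = NULL, lambda = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(structure)) {
    if (is.null(tree)) stop("provide `tree` or `structure`")
    structure <- pgls_structure(tree, design$species, design$weights)
  }
  if (!identical(structure$species, design$species))
    stop("structure species do not match design species/order")
  n <- length(design$y)
  p <- ncol(design$X)
  if (n < p + 1L)
    stop(sprintf("insufficient data: %d species for %d coefficients", n, p))
  isw <- 1 / sqrt(structure$wt)
  u <- drop(crossprod(structure$Q, design$y * isw))
  U <- crossprod(structure$Q, design$X * isw)
  ll <- function(lam) .gls_at_lambda(lam, u, U, structure$evals,
                                     structure$logdet_wt)$loglik
  if (is.null(lambda)) {
    opt <- optimize(ll, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, 1, opt$maximum)
    lls <- c(ll(0), ll(1), opt$objective)
    # prefer a boundary on ties within optimizer tolerance
    best <- which(lls >= max(lls) - 1e-8)[1]
    lambda_hat <- cand[best]
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
    lambda_hat <- lambda
  }
  at <- .gls_at_lambda(lambda_hat, u, U, structure$evals, structure$logdet_wt)
  beta <- setNames(at$beta, colnames(design$X))
  sigma2_hat <- at$rss / (n - p)
  se <- setNames(sqrt(sigma2_hat * diag(solve(at$XtX))), names(beta))
  new_pgls_fit(beta, se, lambda_hat, sigma2_hat, at$loglik, n, p)
}

#' Per-coefficient t-test from a PGLS fit
#'
#' @param fit a `pgls_fit`.
#' @param term coefficient name.
#' @return list with `t` and two-sided `p` on `n - p` degrees of freedom.
#' @export
coefficient_test <- function(fit, term) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (!term %in% names(fit$beta)) stop("unknown term: ", term)
  list(t = unname(fit$tstats[term]), p = unname(fit$pvalues[term]))
}

#' Poisson phylogenetic GLM by generalized estimating equations
#'
#' Log-link Poisson regression of per-species counts on predictors, with
#' phylogenetic dependence handled as a GEE working correlation: the
#' lambda-transformed Brownian correlation of the tree. With
#' `lambda = 0` (or a star tree) the estimating equations are those of an
#' ordinary Poisson GLM and the coefficients match IRLS. Standard errors
#' are model-based GEE errors scaled by the Pearson dispersion; a
#' single phylogeny is one correlated cluster, so the usual cluster
#' sandwich is unavailable (it would be rank one). The quasi-score under a
#' full-strength working correlation does not always have a root; when the
#' damped iteration fails to converge, the working lambda is halved until
#' it does (with a warning; the `lambda` field reports the value used).
#' GEE coefficient estimates remain consistent under any working
#' correlation.
#'
#' @param counts named nonnegative integer vector (species names).
#' @param predictors data.frame/list of named per-species columns.
#' @param tree a `phylo` object.
#' @param lambda working-correlation lambda in \[0, 1\] (default 1, full
#'   Brownian correlation).
#' @param max_iter,tol Fisher-scoring controls.
#' @return an object of class `pglm_fit` with `beta`, `se`, `tstats`
#'   (Wald z), `pvalues`, `dispersion`, `method`.
#' @export
fit_poisson_pglm <- function(counts, predictors, tree, lambda = 1,
                             max_iter = 100, tol = 1e-10) {
  names(counts) <- normalize_species(names(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (all(counts == 0)) stop("degenerate response: all counts are zero")
  predictors <- as.data.frame(predictors, optional = TRUE)
  if (is.null(rownames(predictors)) ||
      identical(rownames(predictors), as.character(seq_len(nrow(predictors)))))
    rownames(predictors) <- names(counts)
  else rownames(predictors) <- normalize_species(rownames(predictors))
  sp <- intersect(names(counts), rownames(predictors))
  sp <- intersect(sp, normalize_species(tree$tip.label))
  y <- counts[sp]
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors[sp, , drop = FALSE]))
  V <- bm_covariance(tree, sp)
  K <- V / sqrt(tcrossprod(diag(V)))
  n <- length(y)
  p <- ncol(X)
  # damped Fisher scoring for the GEE quasi-score under working
  # correlation R; steps are capped so the iteration cannot run away
  gee_solve <- function(Rinv, beta) {
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      mu <- exp(pmin(eta, 30))
      A <- sqrt(mu)
      DA <- X * A                         # diag(A) X = A^{-1} D, D = diag(mu) X
      M <- crossprod(DA, Rinv %*% DA)     # D' Vw^-1 D
      if (rcond(M) < 1e-14) return(NULL)
      s <- crossprod(DA, Rinv %*% ((y - mu) / A))
      step <- drop(solve(M, s))
      cap <- max(abs(step))
      if (cap > 0.5) step <- step * (0.5 / cap)
      beta <- beta + step
      if (max(abs(step)) < tol) return(beta)
    }
    NULL
  }
  # independence start (ordinary Poisson IRLS; always converges here)
  beta0 <- gee_solve(diag(n), c(log(mean(y) + 0.5), rep(0, p - 1)))
  if (is.null(beta0)) stop("Poisson GLM failed to converge")
  # the full-strength phylogenetic working correlation does not always
  # admit a quasi-score root; shrink lambda until the GEE converges
  # (lambda = 0 is the independence GEE and always does)
  lam_try <- unique(c(lambda * 2^-(0:5), 0))
  beta <- NULL
  for (lam in lam_try) {
    R <- lambda_transform(K, lam)
    Rinv <- solve(R)
    beta <- gee_solve(Rinv, beta0)
    if (!is.null(beta)) { lambda_used <- lam; break }
  }
  if (lambda_used != lambda)
    warning(sprintf(
      "GEE did not converge at working lambda %.3g; using lambda %.3g",
      lambda, lambda_used))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  A <- sqrt(mu)
  DA <- X * A
  M <- crossprod(DA, Rinv %*% DA)
  pearson <- (y - mu) / A
  phi <- sum(drop(crossprod(pearson, Rinv %*% pearson))) / (n - p)
  covb <- phi * solve(M)
  se <- sqrt(diag(covb))
  names(se) <- colnames(X)
  beta <- setNames(beta, colnames(X))
  z <- beta / se
  pv <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(beta = beta, se = se, tstats = z, pvalues = pv,
                 dispersion = phi, n = n, p = p, lambda = lambda_used,
                 fitted = mu,
                 method = "poisson-gee-phylo-workingcor-modelSE"),
            class = "pglm_fit")
}

#' @export
print.pglm_fit <- function(x, ...) {
  cat(sprintf("Poisson phylogenetic GLM (%s): n = %d, dispersion = %.3f\n",
              x$method, x$n, x$dispersion))
  print(data.frame(Estimate = x$beta, `Std.Error` = x$se, z = x$tstats,
                   p = x$pvalues, check.names = FALSE), digits = 4)
  invisible(x)
}
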