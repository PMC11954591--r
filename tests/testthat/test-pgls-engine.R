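test_that("fit_gls reduces to the mean and to exact fits", {
  sp <- paste0("s", 1:3)
  y <- setNames(c(1, 2, 3), sp)
  C <- diag(3)
  dimnames(C) <- list(sp, sp)
  des <- design_spec(y, data.frame(row.names = sp))
  f <- fit_gls(des, C)
  expect_equal(unname(f$beta), 2)

  x <- setNames(c(0, 1, 2), sp)
  des2 <- design_spec(setNames(1 + 3 * x, sp), list(x = x))
  f2 <- fit_gls(des2, C)
  expect_equal(unname(f2$beta), c(1, 3), tolerance = 1e-12)
  expect_equal(f2$sigma2_hat, 0, tolerance = 1e-20)
})

test_that("fit_gls equals the normal-equations oracle on random instances", {
  for (s in 1:100) {
    n <- withr::with_seed(2200 + s, sample(5:12, 1))
    tr <- rtree_seeded(n, seed = 2000 + s)
    V <- bm_covariance(tr)
    dat <- withr::with_seed(3000 + s, list(
      y = setNames(rnorm(n), tr$tip.label),
      x1 = setNames(rnorm(n), tr$tip.label),
      x2 = setNames(rnorm(n), tr$tip.label)))
    des <- design_spec(dat$y, list(x1 = dat$x1, x2 = dat$x2))
    f <- fit_gls(des, V)
    o <- gls_oracle(des$y, des$X, V[des$species, des$species])
    expect_equal(unname(f$beta), unname(o$beta), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(o$se), tolerance = 1e-8)
    expect_equal(f$sigma2_hat, o$sigma2, tolerance = 1e-8)
  }
})

test_that("singular designs are rejected with the offending column named", {
  sp <- paste0("s", 1:6)
  y <- setNames(rnorm(6), sp)
  x <- setNames(rnorm(6), sp)
  expect_error(design_spec(y, list(x = x, x2 = 2 * x)), "x2")
})

test_that("profiled lambda beats a 101-point grid and boundary values", {
  tr <- generate_tree(60, seed = 21)
  y <- simulate_bm(tr, 1, 0, seed = 22)
  x <- withr::with_seed(23, setNames(rnorm(60), names(y)))
  des <- design_spec(y, list(x = x))
  fit <- fit_pgls(des, tr)
  grid <- vapply(seq(0, 1, length.out = 101), function(l)
    fit_pgls(des, tr, lambda = l)$loglik, numeric(1))
  expect_true(max(grid) <= fit$loglik + 1e-6)
  expect_gte(fit$loglik, fit_pgls(des, tr, lambda = 0)$loglik)
  expect_gte(fit$loglik, fit_pgls(des, tr, lambda = 1)$loglik)
})

test_that("lambda = 0 with unit weights reduces to OLS", {
  tr <- generate_tree(40, seed = 31)
  dat <- withr::with_seed(32, list(y = rnorm(40), x = rnorm(40)))
  y <- setNames(dat$y, tr$tip.label)
  x <- setNames(dat$x, tr$tip.label)
  f0 <- fit_pgls(design_spec(y, list(x = x)), tr, lambda = 0)
  ols <- lm(dat$y ~ dat$x)
  expect_equal(unname(f0$beta), unname(coef(ols)), tolerance = 1e-10)
})

test_that("weights are relative: doubling them changes nothing", {
  tr <- generate_tree(25, seed = 41)
  dat <- withr::with_seed(42, list(y = rnorm(25), x = rnorm(25),
                                   w = runif(25, 0.5, 4)))
  y <- setNames(dat$y, tr$tip.label)
  x <- setNames(dat$x, tr$tip.label)
  w1 <- setNames(dat$w, tr$tip.label)
  f1 <- fit_pgls(design_spec(y, list(x = x), weights = w1), tr)
  f2 <- fit_pgls(design_spec(y, list(x = x), weights = 2 * w1), tr)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$tstats, f2$tstats, tolerance = 1e-9)
  expect_equal(f1$lambda_hat, f2$lambda_hat, tolerance = 1e-5)
})

test_that("lambda recovery: independent noise gives ~0, pure BM gives ~1", {
  tr <- generate_tree(200, seed = 51)
  st <- pgls_structure(tr)
  cV <- chol(bm_covariance(tr))
  lam0 <- vapply(1:40, function(i) {
    dat <- withr::with_seed(6000 + i, list(y = rnorm(200), x = rnorm(200)))
    des <- design_spec(setNames(dat$y, tr$tip.label),
                       list(x = setNames(dat$x, tr$tip.label)))
    fit_pgls(des, structure = st)$lambda_hat
  }, numeric(1))
  lam1 <- vapply(1:40, function(i) {
    y <- simulate_bm(tr, 1, 0, seed = 7000 + i, chol_V = cV)
    x <- withr::with_seed(8000 + i, setNames(rnorm(200), names(y)))
    fit_pgls(design_spec(y, list(x = x)), structure = st)$lambda_hat
  }, numeric(1))
  expect_lte(median(lam0), 0.15)
  expect_gte(median(lam1), 0.85)
})

test_that("coefficient_test matches the t distribution and is symmetric", {
  fit <- structure(list(beta = c(a = 1.0, b = 0), se = c(a = 0.5, b = 1),
                        n = 32, p = 2,
                        tstats = c(a = 2, b = 0),
                        pvalues = c(a = 2 * pt(2, 30, lower.tail = FALSE),
                                    b = 1)),
                   class = "pgls_fit")
  ct <- coefficient_test(fit, "a")
  expect_equal(ct$t, 2)
  expect_equal(ct$p, 0.05463, tolerance = 1e-3)
  expect_equal(coefficient_test(fit, "b")$p, 1)
  expect_error(coefficient_test(fit, "zz"), "unknown term")

  tr <- generate_tree(20, seed = 61)
  dat <- withr::with_seed(62, list(y = rnorm(20), x = rnorm(20)))
  y <- setNames(dat$y, tr$tip.label)
  x <- setNames(dat$x, tr$tip.label)
  fp <- fit_pgls(design_spec(y, list(x = x)), tr)
  fn <- fit_pgls(design_spec(-y, list(x = x)), tr)
  expect_equal(fp$pvalues[["x"]], fn$pvalues[["x"]], tolerance = 1e-9)
})

test_that("PGLS p-values are uniform under the null", {
  tr <- generate_tree(50, seed = 71)
  st <- pgls_structure(tr)
  cV <- chol(bm_covariance(tr))
  pv <- vapply(1:1000, function(i) {
    y <- simulate_bm(tr, 1, 0, seed = 20000 + i, chol_V = cV)
    x <- withr::with_seed(30000 + i, setNames(rnorm(50), names(y)))
    fit_pgls(design_spec(y, list(x = x)), structure = st)$pvalues[["x"]]
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("fit_poisson_pglm matches IRLS Poisson GLM on a star tree", {
  star <- suppressWarnings(parse_newick(
    paste0("(", paste(sprintf("s%d:1", 1:40), collapse = ","), ");")))
  dat <- withr::with_seed(81, {
    x <- rnorm(40)
    list(x = x, cnt = rpois(40, exp(1 + 0.4 * x)))
  })
  cnt <- setNames(dat$cnt, star$tip.label)
  pf <- fit_poisson_pglm(cnt, list(x = setNames(dat$x, star$tip.label)), star)
  gf <- glm(dat$cnt ~ dat$x, family = poisson)
  expect_equal(unname(pf$beta), unname(coef(gf)), tolerance = 1e-6)
  expect_error(fit_poisson_pglm(setNames(rep(0L, 40), star$tip.label),
                                list(x = setNames(dat$x, star$tip.label)),
                                star),
               "degenerate")
})

test_that("fit_poisson_pglm: null slope covered, planted slope recovered", {
  tr <- generate_tree(40, seed = 91)
  x <- withr::with_seed(92, setNames(rnorm(40), tr$tip.label))
  cnt <- setNames(rep(5L, 40), tr$tip.label)
  f <- fit_poisson_pglm(cnt, list(x = x), tr)
  expect_lt(abs(f$beta[["x"]]), 2 * f$se[["x"]] + 1e-8)
  expect_lt(abs(f$beta[["(Intercept)"]] - log(5)), 0.2)

  tr94 <- generate_tree(94, seed = 93)
  signs <- vapply(1:100, function(i) {
    dat <- withr::with_seed(40000 + i, {
      xx <- rnorm(94)
      list(x = xx, cnt = rpois(94, exp(1 + 0.5 * xx)))
    })
    ff <- suppressWarnings(
      fit_poisson_pglm(setNames(dat$cnt, tr94$tip.label),
                       list(x = setNames(dat$x, tr94$tip.label)), tr94))
    sign(ff$beta[["x"]])
  }, numeric(1))
  expect_gte(sum(signs > 0), 95)
})
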