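test_that("adjust_pvalues matches hand and brute-force oracles", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "hommel"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.2, 1.3), "BH"), "0, 1")

  withr::with_seed(101, {
    for (r in 1:300) {
      p <- runif(sample(1:20, 1))
      expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
    for (r in 1:40) {
      p <- runif(sample(2:5, 1))
      expect_equal(adjust_pvalues(p, "hommel"), hommel_oracle(p),
                   tolerance = 1e-12)
    }
  })
})

test_that("screens run end-to-end; m = 1 gives p_adjusted = p", {
  world <- small_world(seed = 201, n_species = 40, n_orthogroups = 60)
  Mf <- filter_orthogroups(world$M)
  one <- cn_matrix(Mf$counts[1, , drop = FALSE])
  tab <- screen_orthogroups(one, world$phenotypes, "malignancy_rate",
                            world$tree,
                            covariate = proteome_covariate(world$M, "all"))
  expect_equal(tab$p_adjusted, tab$p)
  expect_true(all(tab$p_adjusted >= tab$p - 1e-15))
  expect_equal(nrow(tab), 1L)
})

test_that("screens are invariant to species and orthogroup ordering", {
  world <- small_world(seed = 211, n_species = 30, n_orthogroups = 40)
  Mf <- filter_orthogroups(world$M)
  tab1 <- screen_orthogroups(Mf, world$phenotypes, "longevity", world$tree)
  perm_sp <- withr::with_seed(212, sample(ncol(Mf$counts)))
  perm_og <- withr::with_seed(213, sample(nrow(Mf$counts)))
  M2 <- cn_matrix(Mf$counts[perm_og, perm_sp], Mf$annotation)
  # the proteome covariate must be the same object in both runs
  cov <- proteome_covariate(Mf, "all")
  tabA <- screen_orthogroups(Mf, world$phenotypes, "longevity", world$tree,
                             covariate = cov)
  tabB <- screen_orthogroups(M2, world$phenotypes, "longevity", world$tree,
                             covariate = cov)
  tabB <- tabB[match(tabA$unit, tabB$unit), ]
  expect_equal(tabA$p, tabB$p, tolerance = 1e-9)
  expect_equal(tabA$estimate, tabB$estimate, tolerance = 1e-9)
})

test_that("constant aggregates are flagged untestable, not dropped", {
  world <- small_world(seed = 221, n_species = 25, n_orthogroups = 30)
  cov <- proteome_covariate(world$M, "mouse_annotated")
  aggs <- list(
    const = setNames(rep(7, 25), world$M$species),
    ok = colSums(world$M$counts[1:5, ]))
  tab <- screen_gene_sets(aggs, world$phenotypes, "malignancy_rate",
                          world$tree, cov)
  expect_equal(nrow(tab), 2L)
  expect_false(tab$testable[tab$unit == "const"])
  expect_true(is.na(tab$p[tab$unit == "const"]))
  # BH family excludes the untestable row
  expect_equal(tab$p_adjusted[tab$unit == "ok"], tab$p[tab$unit == "ok"])
})

test_that("a singleton set equals the per-orthogroup test with the same covariate", {
  world <- small_world(seed = 231, n_species = 35, n_orthogroups = 50)
  Mf <- filter_orthogroups(world$M)
  cov <- proteome_covariate(world$M, "mouse_annotated")
  og <- Mf$orthogroups[3]
  tab_og <- screen_orthogroups(cn_matrix(Mf$counts[og, , drop = FALSE]),
                               world$phenotypes, "malignancy_rate",
                               world$tree, covariate = cov)
  tab_set <- screen_gene_sets(list(S = Mf$counts[og, ]), world$phenotypes,
                              "malignancy_rate", world$tree, cov)
  expect_equal(tab_set$p, tab_og$p, tolerance = 1e-9)
  expect_equal(tab_set$estimate, tab_og$estimate, tolerance = 1e-9)
})

test_that("a strongly planted orthogroup ranks first among nulls", {
  hits <- vapply(1:10, function(r) {
    cfg <- sim_config(n_species = 50, n_orthogroups = 200, seed = 2400 + r,
                      planted = list(list(name = "S", size = 1, slope = 0.4,
                                          phenotype = "longevity")))
    sim <- simulate_dataset(cfg)
    Mf <- filter_orthogroups(sim$M)
    tab <- screen_orthogroups(Mf, sim$phenotypes, "longevity", sim$tree)
    tab$unit[1] == sim$mapping$S
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("reverse_pglm_check recovers planted count-on-rate dependence", {
  expect_equal(nrow(reverse_pglm_check(character(0), list(),
                                       data.frame(species = "a"), NULL)), 0L)

  tr <- generate_tree(60, seed = 251)
  hits <- vapply(1:20, function(r) {
    dat <- withr::with_seed(2500 + r, {
      rate <- runif(60, 0.05, 0.95)
      cnt <- rpois(60, exp(2 + 1.5 * rate))
      list(rate = rate, cnt = cnt)
    })
    ph <- derive_cancer_phenotypes(data.frame(
      species = tr$tip.label, n_necropsies = 1000L,
      n_neoplasia = 500L, n_malignant = round(500 * dat$rate)))
    tab <- suppressWarnings(
      reverse_pglm_check("S", list(S = setNames(dat$cnt, tr$tip.label)),
                         ph, tr))
    tab$p[1] < 0.05 && tab$estimate[1] > 0
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("table1_directionality counts negative estimates", {
  fx <- table1_fixture()
  expect_equal(table1_directionality(fx), 11L)
  expect_equal(table1_directionality(data.frame(estimate = c(1, 2, 3))), 0L)
  flipped <- fx
  flipped$estimate <- -flipped$estimate
  expect_equal(table1_directionality(flipped), 1L)
})
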