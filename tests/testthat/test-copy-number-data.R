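test_that("read_counts validates and round-trips", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("orthogroup_id\tMus musculus\tHomo sapiens",
               "OG1\t2\t3", "OG2\t0\t1"), tmp)
  M <- read_counts(tmp)
  expect_equal(unname(M$counts["OG1", ]), c(2L, 3L))
  expect_equal(M$species, c("mus_musculus", "homo_sapiens"))

  writeLines(c("id\ta\tb", "OG1\t-1\t3"), tmp)
  expect_error(read_counts(tmp), "OG1")
  writeLines(c("id\ta\tb", "OG1\t2\t3", "OG1\t0\t1"), tmp)
  expect_error(read_counts(tmp), "duplicate")

  big <- small_world(seed = 9, n_species = 30, n_orthogroups = 500)$M
  out <- tempfile(fileext = ".tsv")
  write_counts(big, out)
  back <- read_counts(out)
  expect_identical(back$counts, big$counts)
})

test_that("filter_orthogroups applies a strict >50% rule and is idempotent", {
  counts94 <- rbind(half = c(rep(1L, 47), rep(0L, 47)),
                    most = c(rep(1L, 48), rep(0L, 46)),
                    all1 = rep(1L, 94))
  colnames(counts94) <- paste0("s", 1:94)
  M <- cn_matrix(counts94)
  kept <- filter_orthogroups(M)
  expect_setequal(kept$orthogroups, c("most", "all1"))

  counts20 <- rbind(eleven = c(rep(1L, 11), rep(0L, 9)),
                    ten = c(rep(1L, 10), rep(0L, 10)))
  colnames(counts20) <- paste0("s", 1:20)
  k20 <- filter_orthogroups(cn_matrix(counts20))
  expect_identical(k20$orthogroups, "eleven")

  twice <- filter_orthogroups(kept)
  expect_identical(twice$counts, kept$counts)
})

test_that("read_gmt parses, deduplicates, and reports bad lines", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c(paste(c("SET_A", "na", letters[1:12]), collapse = "\t"),
               paste(c("SET_B", "na", "x", "y", "x"), collapse = "\t")), tmp)
  gs <- read_gmt(tmp)
  expect_length(gs[["SET_A"]], 12)
  expect_length(gs[["SET_B"]], 2)

  writeLines(c("GOOD\tna\ta", "BAD\tna"), tmp)
  expect_error(read_gmt(tmp), "line 2")
})

test_that("MSigDB-dialect GMT fixture loads with URL description ignored", {
  gs <- read_gmt(system.file("extdata", "example_sets.gmt",
                             package = "cnpgls"))
  expect_true("GOBP_NEG_REG_TGFB_PRODUCTION" %in% names(gs))
  expect_length(gs[["GOBP_NEG_REG_TGFB_PRODUCTION"]], 12)
  expect_true("Tsku" %in% gs[["GOBP_NEG_REG_TGFB_PRODUCTION"]])
})

test_that("map_sets_to_orthogroups follows the annotation contract", {
  counts <- matrix(1L, 3, 4,
                   dimnames = list(c("OG1", "OG2", "OG3"), paste0("s", 1:4)))
  M <- cn_matrix(counts, annotation = list(OG1 = "Tp53",
                                           OG2 = c("Brca1", "Met")))
  sets <- gene_sets(list(P53 = "TP53", TWO = c("brca1", "MET"),
                         NONE = "Zzz"))
  map <- suppressWarnings(map_sets_to_orthogroups(sets, M))
  expect_identical(map$P53, "OG1")
  expect_identical(map$TWO, "OG2")
  expect_false("NONE" %in% names(map))

  # brute-force membership scan on a random annotation fixture
  world <- small_world(seed = 13, n_species = 20, n_orthogroups = 80)
  M2 <- world$M
  syms <- unlist(M2$annotation, use.names = FALSE)
  rsets <- withr::with_seed(14, gene_sets(list(
    R1 = sample(syms, 10), R2 = sample(syms, 25))))
  map2 <- map_sets_to_orthogroups(rsets, M2)
  for (nm in names(map2)) {
    brute <- names(Filter(function(a)
      any(tolower(a) %in% tolower(rsets[[nm]])), M2$annotation))
    expect_setequal(map2[[nm]], brute)
  }
})

test_that("aggregate_set_counts sums rows once each, in any order", {
  counts <- rbind(OG1 = c(1L, 2L), OG2 = c(3L, 0L), OG3 = c(2L, 5L))
  colnames(counts) <- c("sa", "sb")
  M <- cn_matrix(counts)
  mapping <- list(S = c("OG1", "OG2"), S1 = "OG1", S2 = "OG2",
                  Srev = c("OG2", "OG1"))
  expect_equal(aggregate_set_counts(M, mapping, "S"), c(sa = 4, sb = 2))
  expect_equal(aggregate_set_counts(M, mapping, "S1"), c(sa = 1, sb = 2))
  # permutation invariance and additivity over a partition
  expect_equal(aggregate_set_counts(M, mapping, "Srev"),
               aggregate_set_counts(M, mapping, "S"))
  expect_equal(aggregate_set_counts(M, mapping, "S1") +
                 aggregate_set_counts(M, mapping, "S2"),
               aggregate_set_counts(M, mapping, "S"))
  expect_error(aggregate_set_counts(M, list(), "S"), "no mapping")
})

test_that("derive_cancer_phenotypes computes rates, weights, and exclusions", {
  raw <- data.frame(species = c("A b", "C_d", "E f"),
                    n_necropsies = c(25L, 100L, 30L),
                    n_neoplasia = c(10L, 20L, 0L),
                    n_malignant = c(4L, 5L, 0L))
  ph <- derive_cancer_phenotypes(raw)
  expect_equal(ph$malignancy_rate[1], 0.4)
  expect_equal(ph$weight[1], 5)
  expect_true(is.na(ph$malignancy_rate[3]))
  expect_equal(ph$species, c("a_b", "c_d", "e_f"))
  # identity: rate * neoplasia prevalence = malignancy prevalence
  def <- !is.na(ph$malignancy_rate)
  expect_equal(ph$malignancy_rate[def] * ph$neoplasia_prevalence[def],
               ph$malignancy_prevalence[def], tolerance = 1e-12)
  expect_true(all(ph$neoplasia_prevalence >= ph$malignancy_prevalence))

  bad <- raw
  bad$n_malignant[1] <- 11L
  expect_error(derive_cancer_phenotypes(bad), "exceeds")
})

test_that("proteome_covariate modes behave as masked column sums", {
  counts <- rbind(OG1 = c(1L, 2L), OG2 = c(3L, 4L))
  colnames(counts) <- c("sa", "sb")
  M_none <- cn_matrix(counts)
  expect_warning(z <- proteome_covariate(M_none, "mouse_annotated"),
                 "all zero")
  expect_equal(unname(z), c(0, 0))

  M_all <- cn_matrix(counts, annotation = list(OG1 = "a", OG2 = "b"))
  expect_equal(proteome_covariate(M_all, "all"),
               proteome_covariate(M_all, "mouse_annotated"))

  M_mix <- cn_matrix(counts, annotation = list(OG2 = "b"))
  expect_equal(proteome_covariate(M_mix, "mouse_annotated"),
               colSums(counts["OG2", , drop = FALSE]))
})
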