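test_that("balanced recipes keep the top-quota by confidence with index ties", {
  reg <- list(herb = "H1", tcm_symptom = "S1", mm_symptom = "M1",
              disease = "D1", target = paste0("T", 1:6), pathway = "P1")
  em <- function(nr, nc) Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(),
                                              dims = c(nr, nc))
  it <- data.frame(herb = 1L, target = c(1L, 2L, 3L),
                   confidence = c(0.3, 0.2, 0.25), p_value = 0.01)
  kb <- knowledgeBase(reg, em(1, 1), em(1, 1), em(1, 1), em(1, 6), it)
  ds <- buildDataset(kb, datasetRecipe("b2", 0, 1, "balanced", quota = 2))
  expect_setequal(positives(ds)$confidence, c(0.3, 0.25))
  ## imbalanced with the same minimum keeps all three
  ds2 <- buildDataset(kb, datasetRecipe("m2", 0, 1, "imbalanced",
                                        minRequired = 2))
  expect_equal(nrow(positives(ds2)), 3L)
  ## confidence ties break by ascending target index
  it3 <- data.frame(herb = 1L, target = c(5L, 2L, 4L),
                    confidence = 0.5, p_value = 0.01)
  kb3 <- knowledgeBase(reg, em(1, 1), em(1, 1), em(1, 1), em(1, 6), it3)
  ds3 <- buildDataset(kb3, datasetRecipe("b2", 0, 1, "balanced", quota = 2))
  expect_setequal(positives(ds3)$target, c(2L, 4L))
})

test_that("the significance threshold and confidence band filter first", {
  kb <- makeToyKb()
  ## p = 0.2 record (herb 5) and confidence 0.3 record (herb 4) are excluded
  ds <- buildDataset(kb, datasetRecipe("r", 0.4, 1, "imbalanced",
                                       minRequired = 1))
  expect_false(5L %in% positives(ds)$herb)
  expect_false(4L %in% positives(ds)$herb)
  expect_error(buildDataset(kb, datasetRecipe("none", 0.97, 1, "imbalanced",
                                              minRequired = 1)),
               "empty dataset")
})

test_that("engineered fixed-quota bases produce herbs x quota positives", {
  kb <- makeRecipeKb(nHerbs = 12L, perHerb = 3L, band = c(0.18, 0.5))
  ds <- buildDataset(kb, datasetRecipe("q3", 0.18, 0.5, "balanced",
                                       quota = 3))
  expect_equal(length(eligibleHerbs(ds)), 12L)
  expect_equal(nrow(positives(ds)), 36L)
  tab <- table(positives(ds)$herb)
  expect_true(all(tab == 3L))
})

test_that("cold-start folds partition herbs exactly once into test", {
  ds <- buildDataset(smallSynthKb()$kb,
                     datasetRecipe("all", 0, 1, "imbalanced",
                                   minRequired = 1))
  sp <- coldStartSplit(ds, 5, seed = 3)
  testSets <- lapply(sp$folds, `[[`, "test")
  expect_setequal(unlist(testSets), eligibleHerbs(ds))
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(testSets[[i]], testSets[[j]]), 0L)
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$validation, f$test), 0L)
    sizes <- table(unlist(lapply(testSets, length)))
    expect_lte(diff(range(lengths(testSets))), 1L)
  }
  expect_identical(coldStartSplit(ds, 5, seed = 3)$folds, sp$folds)
  expect_error(coldStartSplit(ds, length(eligibleHerbs(ds)) + 1L), "fewer")
})

test_that("decoys never collide with any known positive of their herb", {
  g <- smallSynthKb()
  kb <- g$kb
  gr <- suppressWarnings(buildGraph(kb))
  ds <- buildDataset(kb, datasetRecipe("all", 0, 1, "imbalanced",
                                       minRequired = 1))
  known <- split(kb@interactions$target, kb@interactions$herb)
  for (strategy in c("random", "degree_matched", "pathway_constrained")) {
    for (ep in 1:3) {
      dec <- suppressWarnings(
        sampleNegatives(ds, gr, kb, strategy = strategy, epochSeed = ep))
      expect_equal(nrow(dec), nrow(positives(ds)))   # exactly 1:1
      bad <- mapply(function(h, d) d %in% known[[as.character(h)]],
                    dec$herb, dec$decoy)
      expect_false(any(bad), label = paste(strategy, ep))
    }
  }
})

test_that("dynamic sampling changes decoys across epoch seeds", {
  g <- smallSynthKb()
  gr <- suppressWarnings(buildGraph(g$kb))
  ds <- buildDataset(g$kb, datasetRecipe("all", 0, 1, "imbalanced",
                                         minRequired = 1))
  d1 <- sampleNegatives(ds, gr, g$kb, strategy = "random", epochSeed = 1)
  d2 <- sampleNegatives(ds, gr, g$kb, strategy = "random", epochSeed = 2)
  expect_true(any(d1$decoy != d2$decoy))
  expect_identical(d1, sampleNegatives(ds, gr, g$kb, strategy = "random",
                                       epochSeed = 1))
})

test_that("a herb interacting with every target has no decoy pool", {
  reg <- list(herb = "H1", tcm_symptom = "S1", mm_symptom = "M1",
              disease = "D1", target = c("T1", "T2"), pathway = "P1")
  em <- function(nr, nc) Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(),
                                              dims = c(nr, nc))
  it <- data.frame(herb = 1L, target = 1:2, confidence = 0.5,
                   p_value = 0.01)
  kb <- knowledgeBase(reg, em(1, 1), em(1, 1), em(1, 1), em(1, 2), it)
  ds <- buildDataset(kb, datasetRecipe("all", 0, 1, "imbalanced",
                                       minRequired = 1))
  g <- suppressWarnings(buildGraph(kb))
  expect_error(sampleNegatives(ds, g, kb, strategy = "random"),
               "empty decoy pool")
})

test_that("degree matching reduces to random when all degrees are equal", {
  ## ring of binary PPIs: every target has degree 2
  nT <- 10L
  reg <- list(herb = c("H1", "H2"), tcm_symptom = "S1", mm_symptom = "M1",
              disease = "D1", target = paste0("T", 1:nT), pathway = "P1")
  em <- function(nr, nc) Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(),
                                              dims = c(nr, nc))
  ppi <- data.frame(src = 1:nT, dst = c(2:nT, 1L), category = "binary",
                    combined_score = 900L)
  ppi[ppi$src > ppi$dst, c("src", "dst")] <- ppi[ppi$src > ppi$dst,
                                                 c("dst", "src")]
  it <- data.frame(herb = c(1L, 2L), target = c(1L, 5L), confidence = 0.5,
                   p_value = 0.01)
  kb <- knowledgeBase(reg, em(2, 1), em(1, 1), em(1, 1), em(1, nT), it, ppi)
  g <- suppressWarnings(buildGraph(kb, 700))
  ds <- buildDataset(kb, datasetRecipe("all", 0, 1, "imbalanced",
                                       minRequired = 1))
  ## with all degrees equal the degree-matched candidate pool is the whole
  ## unobserved space, so repeated draws must cover it like random draws do
  seen <- lapply(1:2, function(i) integer())
  for (ep in 1:80) {
    dm <- sampleNegatives(ds, g, kb, strategy = "degree_matched",
                          epochSeed = ep)
    for (i in 1:2) seen[[i]] <- union(seen[[i]], dm$decoy[i])
  }
  for (i in 1:2) {
    pool <- setdiff(seq_len(nT), it$target[i])
    expect_setequal(seen[[i]], pool)
  }
})

test_that("pathway-constrained decoys come from shared KEGG pathways", {
  ## targets a=1, b=2 share KEGG P1; c=3 does not; positive (h, a) and
  ## (h, b) unknown: the only admissible decoy is b
  reg <- list(herb = "H1", tcm_symptom = "S1", mm_symptom = "M1",
              disease = "D1", target = c("Ta", "Tb", "Tc"),
              pathway = c("P1", "P2"))
  em <- function(nr, nc) Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(),
                                              dims = c(nr, nc))
  ann <- data.frame(target = c(1L, 2L, 3L), pathway = c(1L, 1L, 2L),
                    type = c("KEGG", "KEGG", "KEGG"))
  it <- data.frame(herb = 1L, target = 1L, confidence = 0.5, p_value = 0.01)
  kb <- knowledgeBase(reg, em(1, 1), em(1, 1), em(1, 1), em(1, 3), it,
                      annotations = ann)
  g <- suppressWarnings(buildGraph(kb))
  ds <- buildDataset(kb, datasetRecipe("all", 0, 1, "imbalanced",
                                       minRequired = 1))
  for (ep in 1:5) {
    dec <- sampleNegatives(ds, g, kb, strategy = "pathway_constrained",
                           epochSeed = ep)
    expect_equal(dec$decoy, 2L)
  }
})
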