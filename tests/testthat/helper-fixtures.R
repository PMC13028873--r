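## Fixtures built in code: a fully explicit 5-herb toy knowledge base and
## small seeded synthetic bases.

library(Matrix)

## 5 herbs, 5 TCM symptoms, 3 MM symptoms, 4 diseases, 6 targets, 3 pathways.
makeToyKb <- function() {
  reg <- list(herb = paste0("H", 1:5), tcm_symptom = paste0("S", 1:5),
              mm_symptom = paste0("M", 1:3), disease = paste0("D", 1:4),
              target = paste0("T", 1:6), pathway = paste0("P", 1:3))
  M_HT <- sparseMatrix(i = c(1, 1, 2, 2, 3, 4, 5, 5),
                       j = c(1, 4, 2, 3, 1, 5, 2, 4),
                       x = 1, dims = c(5, 5))
  M_TM <- sparseMatrix(i = c(1, 2, 3, 4, 5), j = c(1, 2, 2, 3, 1),
                       x = c(1, 0.9, 1, 0.85, 1), dims = c(5, 3))
  M_MD <- sparseMatrix(i = c(1, 1, 2, 3), j = c(1, 2, 3, 4),
                       x = c(1, 0.95, 1, 1), dims = c(3, 4))
  M_DT <- sparseMatrix(i = c(1, 2, 2, 3, 4, 4), j = c(1, 2, 3, 4, 5, 6),
                       x = c(1, 1, 0.9, 1, 1, 0.88), dims = c(4, 6))
  interactions <- data.frame(
    herb = c(1L, 1L, 2L, 3L, 4L, 5L),
    target = c(1L, 3L, 2L, 4L, 5L, 6L),
    confidence = c(0.9, 0.4, 0.7, 0.95, 0.3, 0.6),
    p_value = c(0.01, 0.02, 0.04, 0.001, 0.03, 0.2))
  ppis <- data.frame(
    src = c(1L, 2L, 1L, 5L, 3L),
    dst = c(2L, 3L, 4L, 6L, 5L),
    category = c("binary", "kinase", "complexes", "signaling", "literature"),
    combined_score = c(950L, 800L, 720L, 650L, 900L))
  annotations <- data.frame(
    target = c(1L, 2L, 2L, 4L, 5L),
    pathway = c(1L, 1L, 2L, 3L, 3L),
    type = c("KEGG", "KEGG", "GO_BP", "GO_MF", "GO_MF"))
  knowledgeBase(reg, M_HT, M_TM, M_MD, M_DT, interactions, ppis, annotations)
}

## Small planted synthetic base for integration-style tests.
smallSynthKb <- function(seed = 7L) {
  generateKnowledgeBase(synthConfig(
    nHerbs = 40L, nTcm = 30L, nMm = 20L, nDisease = 30L, nTarget = 120L,
    nPathway = 15L, nMechanisms = 4L, seed = seed))
}

## Knowledge base engineered to a fixed-quota recipe row: `nHerbs` herbs
## with exactly `perHerb` interactions inside the confidence band (plus one
## sub-threshold herb and some out-of-band records to give the filters work).
makeRecipeKb <- function(nHerbs, perHerb, band = c(0.18, 0.5), seed = 1L) {
  nT <- max(2L * perHerb + 10L, 50L)
  nH <- nHerbs + 1L
  reg <- list(herb = paste0("H", seq_len(nH)),
              tcm_symptom = paste0("S", 1:4),
              mm_symptom = paste0("M", 1:2), disease = paste0("D", 1:2),
              target = paste0("T", seq_len(nT)), pathway = paste0("P", 1:2))
  em <- function(nr, nc) sparseMatrix(i = integer(), j = integer(),
                                      x = numeric(), dims = c(nr, nc))
  M_HT <- sparseMatrix(i = seq_len(nH), j = rep(1L, nH), x = 1,
                       dims = c(nH, 4))
  set.seed(seed)
  rows <- lapply(seq_len(nHerbs), function(h) {
    data.frame(herb = h, target = sample(nT, perHerb),
               confidence = runif(perHerb, band[1], band[2]),
               p_value = runif(perHerb) * 0.04)
  })
  ## one herb below quota and some out-of-band / non-significant records
  extra <- data.frame(herb = nH,
                      target = seq_len(max(perHerb - 1L, 1L)),
                      confidence = runif(max(perHerb - 1L, 1L),
                                         band[1], band[2]),
                      p_value = 0.01)
  junk <- data.frame(herb = c(1L, 2L), target = c(nT, nT - 1L),
                     confidence = c(min(band[1] / 2, 0.01),
                                    min(1, band[2] + 0.2)),
                     p_value = c(0.01, 0.01))
  sig <- data.frame(herb = 3L, target = nT - 2L,
                    confidence = mean(band), p_value = 0.5)
  interactions <- rbind(do.call(rbind, rows), extra, junk, sig)
  interactions <- interactions[!duplicated(interactions[c("herb", "target")]), ]
  knowledgeBase(reg, M_HT, em(4, 2), em(2, 2), em(2, nT), interactions)
}
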