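## Seeded generator of SymMap-like knowledge bases with planted mechanism
## structure. Every entity (symptom, disease, target, pathway) belongs to one
## or two latent mechanisms; herbs carry a mixture over mechanisms. The
## phenotype cascade (TCM symptom -> MM symptom -> disease -> target) is wired
## mechanism-consistently, herb-target positives are drawn with probability
## proportional to mechanism overlap, and PPIs follow a stochastic block model
## over mechanisms. The planted signal is what makes cold-start recovery,
## cascade usefulness, PPI-type ablation and pathway-sparsity strata testable
## without any external download.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the synthetic knowledge-base generator
#'
#' Defaults give the package's reference study condition: 200 herbs, 100 TCM
#' symptoms, 60 modern symptoms, 120 diseases, 800 targets, 60 pathways and
#' 8 planted mechanisms — a scaled-down analogue of a curated multi-scale
#' herbal pharmacology hierarchy.
#'
#' @param nHerbs,nTcm,nMm,nDisease,nTarget,nPathway entity counts.
#' @param nMechanisms number of planted mechanisms.
#' @param overlap probability that an entity belongs to a second mechanism.
#' @param cascadeDensity within-mechanism link probability for each cascade
#'   relation (TM, MD, DT).
#' @param cascadeNoise cross-mechanism link probability for cascade relations.
#' @param symptomsPerHerb expected number of TCM symptoms per herb.
#' @param symptomNoiseRate flip-noise rate on herb symptom profiles in [0,1).
#' @param interactionNoiseRate fraction of positives replaced by uniformly
#'   random targets in [0,1).
#' @param confidenceBand interval (low, high) within (0,1] for interaction
#'   confidence scores, drawn uniformly.
#' @param ppiWithinMechProb,ppiBetweenMechProb stochastic-block-model edge
#'   probabilities for PPIs (within must exceed between).
#' @param ppiCategoryProps named proportions over the seven PPI categories
#'   for the within-mechanism pool. The kinase category is sampled only
#'   within mechanisms (mechanism-informative by construction) while binary
#'   edges take an extra helping of between-mechanism noise, so collapsing
#'   PPI types discards a real signal.
#' @param powerLawExponent exponent of the truncated discrete power law for
#'   per-herb positive counts (long-tail; default 1.6).
#' @param propensityExponent sharpening exponent on the propensity when
#'   sampling positives (higher concentrates positives on the strongest
#'   mechanism matches; as it grows and noise vanishes the propensity
#'   ranking of positives versus random decoys approaches perfection).
#' @param minPositives,maxPositives support of the per-herb positive count.
#' @param annotationsPerTarget expected pathway annotations per target.
#' @param sparseAnnotationFraction fraction of targets downsampled to fewer
#'   than 3 annotations (the sparse-annotation stratum).
#' @param seed integer RNG seed; generation is fully reproducible from it.
#' @return validated list of class "SynthConfig".
#' @export
synthConfig <- function(nHerbs = 200L, nTcm = 100L, nMm = 60L,
                        nDisease = 120L, nTarget = 800L, nPathway = 60L,
                        nMechanisms = 8L, overlap = 0.15,
                        cascadeDensity = 0.25, cascadeNoise = 0.004,
                        symptomsPerHerb = 8, symptomNoiseRate = 0.02,
                        interactionNoiseRate = 0.05,
                        confidenceBand = c(0.05, 0.95),
                        ppiWithinMechProb = 0.03,
                        ppiBetweenMechProb = 0.001,
                        ppiCategoryProps = c(binary = 0.2, complexes = 0.15,
                                             kinase = 0.2, literature = 0.15,
                                             metabolic = 0.1, regulatory = 0.1,
                                             signaling = 0.1),
                        powerLawExponent = 1.6, propensityExponent = 3,
                        minPositives = 1L, maxPositives = 60L,
                        annotationsPerTarget = 4,
                        sparseAnnotationFraction = 0.3,
                        seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(nHerbs, nTcm, nMm, nDisease, nTarget, nPathway, nMechanisms)
  stopifnot(all(counts >= 1), ppiWithinMechProb > ppiBetweenMechProb,
            confidenceBand[1] < confidenceBand[2],
            confidenceBand[1] > 0, confidenceBand[2] <= 1,
            symptomNoiseRate >= 0, symptomNoiseRate < 1,
            interactionNoiseRate >= 0, interactionNoiseRate < 1,
            all(names(ppiCategoryProps) %in% .PPI_CATEGORIES))
  class(cfg) <- "SynthConfig"
  cfg
}

## One-or-two-mechanism membership matrix, n x K logical.
.mechMembership <- function(n, K, overlap) {
  m <- matrix(FALSE, n, K)
  primary <- sample.int(K, n, replace = TRUE)
  m[cbind(seq_len(n), primary)] <- TRUE
  second <- which(stats::runif(n) < overlap)
  if (length(second)) {
    alt <- (primary[second] + sample.int(K - 1L, length(second),
                                         replace = TRUE) - 1L) %% K + 1L
    m[cbind(second, alt)] <- TRUE
  }
  m
}

## Mechanism-consistent bipartite wiring with confidence weights. Most
## weights sit in [0.8, 1] (surviving the default QC threshold), a tenth in
## [0.3, 0.8) so the QC filter has work to do.
.cascadeMatrix <- function(memA, memB, within, noise) {
  share <- (memA %*% t(memB)) > 0
  p <- ifelse(share, within, noise)
  hit <- which(matrix(stats::runif(length(p)), nrow(p)) < p)
  if (!length(hit)) stop("cascade relation came out empty; raise density")
  w <- ifelse(stats::runif(length(hit)) < 0.9,
              stats::runif(length(hit), 0.8, 1),
              stats::runif(length(hit), 0.3, 0.8))
  Matrix::sparseMatrix(i = ((hit - 1L) %% nrow(p)) + 1L,
                       j = ((hit - 1L) %/% nrow(p)) + 1L,
                       x = w, dims = dim(p))
}

## Truncated discrete power law P(n) ~ n^-a on lo..hi.
.powerLawCounts <- function(nDraw, a, lo, hi) {
  support <- lo:hi
  p <- support^(-a)
  sample(support, nDraw, replace = TRUE, prob = p / sum(p))
}

.samplePpis <- function(cfg, targetMech) {
  K <- cfg$nMechanisms
  withinPairs <- do.call(rbind, lapply(seq_len(K), function(k) {
    idx <- which(targetMech[, k])
    if (length(idx) < 2) return(NULL)
    t(utils::combn(idx, 2L))
  }))
  withinPairs <- unique(withinPairs)
  nBetweenTry <- stats::rbinom(1, cfg$nTarget * (cfg$nTarget - 1L) / 2L,
                               cfg$ppiBetweenMechProb)
  a <- sample.int(cfg$nTarget, nBetweenTry, replace = TRUE)
  b <- sample.int(cfg$nTarget, nBetweenTry, replace = TRUE)
  keep <- a != b
  betweenPairs <- unique(cbind(pmin(a[keep], b[keep]),
                               pmax(a[keep], b[keep])))
  ## drop between-pairs that are actually within a shared mechanism
  shared <- rowSums(targetMech[betweenPairs[, 1], , drop = FALSE] &
                    targetMech[betweenPairs[, 2], , drop = FALSE]) > 0
  betweenPairs <- betweenPairs[!shared, , drop = FALSE]

  props <- cfg$ppiCategoryProps / sum(cfg$ppiCategoryProps)
  out <- list()
  for (cat in names(props)) {
    pw <- cfg$ppiWithinMechProb * props[[cat]] * 7
    nW <- nrow(withinPairs)
    selW <- withinPairs[stats::runif(nW) < pw, , drop = FALSE]
    if (cat == "kinase") {
      selB <- matrix(integer(), 0, 2)      # strictly mechanism-informative
    } else {
      pb <- props[[cat]] * if (cat == "binary") 3 else 1
      selB <- betweenPairs[stats::runif(nrow(betweenPairs)) < pb, ,
                           drop = FALSE]
    }
    pair <- rbind(selW, selB)
    if (!nrow(pair)) next
    isWithin <- c(rep(TRUE, nrow(selW)), rep(FALSE, nrow(selB)))
    score <- ifelse(isWithin,
                    ifelse(stats::runif(nrow(pair)) < 0.85,
                           sample(700:1000, nrow(pair), replace = TRUE),
                           sample(400:699, nrow(pair), replace = TRUE)),
                    sample(300:900, nrow(pair), replace = TRUE))
    if (cat %in% .PPI_DIRECTED) {
      flip <- stats::runif(nrow(pair)) < 0.5
      src <- ifelse(flip, pair[, 2], pair[, 1])
      dst <- ifelse(flip, pair[, 1], pair[, 2])
    } else {
      src <- pair[, 1]; dst <- pair[, 2]
    }
    out[[cat]] <- data.frame(src = as.integer(src), dst = as.integer(dst),
                             category = cat,
                             combined_score = as.integer(score))
  }
  pp <- do.call(rbind, out)
  rownames(pp) <- NULL
  pp[!duplicated(pp[c("src", "dst", "category")]), ]
}

#' Generate a synthetic knowledge base with planted mechanisms
#'
#' @param cfg a [synthConfig()].
#' @return list with elements `kb` (a [KnowledgeBase-class]) and `truth`
#'   (mechanism memberships, herb mixture weights and the true herb-target
#'   propensity matrix, the Bayes-reference ranking for evaluation).
#' @export
generateKnowledgeBase <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  .withSeed(cfg$seed, {
    K <- cfg$nMechanisms
    mech <- list(
      tcm     = .mechMembership(cfg$nTcm, K, cfg$overlap),
      mm      = .mechMembership(cfg$nMm, K, cfg$overlap),
      disease = .mechMembership(cfg$nDisease, K, cfg$overlap),
      target  = .mechMembership(cfg$nTarget, K, cfg$overlap),
      pathway = .mechMembership(cfg$nPathway, K, cfg$overlap))

    ## herb mechanism mixtures: a dominant primary mechanism, plus a weaker
    ## secondary one for a third of the herbs
    herbMix <- matrix(0, cfg$nHerbs, K)
    for (h in seq_len(cfg$nHerbs)) {
      k1 <- sample.int(K, 1L)
      if (stats::runif(1) < 1 / 3) {
        k2 <- (k1 + sample.int(K - 1L, 1L) - 1L) %% K + 1L
        w2 <- stats::runif(1, 0.1, 0.4)
        herbMix[h, c(k1, k2)] <- c(1 - w2, w2)
      } else {
        herbMix[h, k1] <- 1
      }
    }

    ## cascade matrices (mechanism-consistent)
    M_TM <- .cascadeMatrix(mech$tcm, mech$mm, cfg$cascadeDensity,
                           cfg$cascadeNoise)
    M_MD <- .cascadeMatrix(mech$mm, mech$disease, cfg$cascadeDensity,
                           cfg$cascadeNoise)
    M_DT <- .cascadeMatrix(mech$disease, mech$target,
                           cfg$cascadeDensity * 0.6, cfg$cascadeNoise)

    ## herb symptom profiles from the mechanism mixture, with flip noise
    affinity <- herbMix %*% t(mech$tcm * 1)            # nHerbs x nTcm
    rs <- rowSums(affinity); rs[rs == 0] <- 1
    p <- pmin(affinity / rs * cfg$symptomsPerHerb, 0.95)
    prof <- matrix(stats::runif(length(p)), nrow(p)) < p
    if (cfg$symptomNoiseRate > 0) {
      onFlip <- cfg$symptomNoiseRate * cfg$symptomsPerHerb /
        max(cfg$nTcm - cfg$symptomsPerHerb, 1)
      flip <- matrix(stats::runif(length(prof)), nrow(prof)) <
        ifelse(prof, cfg$symptomNoiseRate, onFlip)
      prof <- xor(prof, flip)
    }
    empty <- which(rowSums(prof) == 0)
    for (h in empty) prof[h, sample.int(cfg$nTcm, 1)] <- TRUE
    M_HT <- .asSparse(Matrix::Matrix(prof * 1, sparse = TRUE))

    ## herb-target positives: long-tail counts, propensity-weighted draws.
    ## Per-target mechanism affinities are graded (not 0/1) so the true
    ## propensity is continuous; the sharpening exponent concentrates the
    ## draws on the strongest mechanism matches.
    affinity <- (mech$target * 1) *
      matrix(stats::runif(cfg$nTarget * K, 0.5, 1), cfg$nTarget, K)
    propensity <- herbMix %*% t(affinity)
    counts <- .powerLawCounts(cfg$nHerbs, cfg$powerLawExponent,
                              min(cfg$minPositives, cfg$nTarget - 1L),
                              min(cfg$maxPositives, cfg$nTarget - 1L))
    pos <- vector("list", cfg$nHerbs)
    for (h in seq_len(cfg$nHerbs)) {
      w <- propensity[h, ]^cfg$propensityExponent
      if (all(w == 0)) w[] <- 1
      ## a long-tail draw cannot exceed the herb's mechanism-matched pool
      tg <- sample.int(cfg$nTarget, min(counts[h], sum(w > 0)), prob = w)
      nNoise <- stats::rbinom(1, counts[h], cfg$interactionNoiseRate)
      if (nNoise > 0)
        tg[seq_len(nNoise)] <- sample.int(cfg$nTarget, nNoise)
      tg <- unique(tg)
      pos[[h]] <- data.frame(herb = h, target = tg)
    }
    interactions <- do.call(rbind, pos)
    nI <- nrow(interactions)
    interactions$confidence <- stats::runif(nI, cfg$confidenceBand[1],
                                            cfg$confidenceBand[2])
    interactions$p_value <- ifelse(stats::runif(nI) < 0.95,
                                   stats::runif(nI) * 0.05,
                                   stats::runif(nI, 0.05, 1))

    ppis <- .samplePpis(cfg, mech$target)

    ## pathway annotations, mechanism-consistent; one origin type per pathway
    pwType <- rep(.ANNOTATION_TYPES, c(
      ceiling(cfg$nPathway * 0.4),
      rep(ceiling(cfg$nPathway * 0.2), 3)))[seq_len(cfg$nPathway)]
    annShare <- (mech$target %*% t(mech$pathway)) > 0
    pAnn <- pmin(annShare * cfg$annotationsPerTarget /
                   pmax(rowSums(annShare), 1), 0.95)
    hit <- which(matrix(stats::runif(length(pAnn)), nrow(pAnn)) < pAnn)
    annotations <- data.frame(
      target = ((hit - 1L) %% cfg$nTarget) + 1L,
      pathway = ((hit - 1L) %/% cfg$nTarget) + 1L)
    annotations$type <- pwType[annotations$pathway]
    ## sparse-annotation stratum: downsample a fraction of targets to < 3
    sparseT <- sample.int(cfg$nTarget,
                          round(cfg$sparseAnnotationFraction * cfg$nTarget))
    keepRow <- rep(TRUE, nrow(annotations))
    for (tg in sparseT) {
      rows <- which(annotations$target == tg)
      if (length(rows) > 2) {
        keepN <- sample(0:2, 1)
        drop <- if (keepN == 0) rows else rows[-sample(seq_along(rows), keepN)]
        keepRow[drop] <- FALSE
      }
    }
    annotations <- annotations[keepRow, ]
    annotations <- annotations[!duplicated(annotations), ]
    annotations <- annotations[order(annotations$target,
                                     annotations$pathway), ]
    rownames(annotations) <- NULL

    pad <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
    reg <- list(herb = pad("H", cfg$nHerbs), tcm_symptom = pad("TS", cfg$nTcm),
                mm_symptom = pad("MS", cfg$nMm),
                disease = pad("D", cfg$nDisease),
                target = pad("T", cfg$nTarget),
                pathway = pad("P", cfg$nPathway))
    kb <- knowledgeBase(reg, M_HT, M_TM, M_MD, M_DT,
                        interactions, ppis, annotations)
    truth <- list(herbMix = herbMix, mechanisms = mech,
                  propensity = propensity, config = cfg)
    class(truth) <- "GroundTruth"
    list(kb = kb, truth = truth)
  })
}

#' Summary table of a knowledge base
#'
#' Entity counts, per-relation edge counts and target-degree quantiles
#' (distinct PPI partners). Never mutates its input.
#'
#' @param kb a KnowledgeBase.
#' @return list with `entities`, `edges` and `targetDegreeQuantiles`.
#' @export
summarizeKnowledgeBase <- function(kb) {
  n <- entityCounts(kb)
  edges <- c(HT = length(kb@M_HT@x), TM = length(kb@M_TM@x),
             MD = length(kb@M_MD@x), DT = length(kb@M_DT@x),
             ppi = nrow(kb@ppis), annotation = nrow(kb@annotations),
             interaction = nrow(kb@interactions))
  deg <- integer(n[["target"]])
  if (nrow(kb@ppis)) {
    partners <- rbind(cbind(kb@ppis$src, kb@ppis$dst),
                      cbind(kb@ppis$dst, kb@ppis$src))
    partners <- unique(partners)
    tab <- table(factor(partners[, 1], levels = seq_len(n[["target"]])))
    deg <- as.integer(tab)
  }
  list(entities = n, edges = edges,
       targetDegreeQuantiles = stats::quantile(deg, c(0, .25, .5, .75, 1)))
}

#' Export ground truth as JSON
#'
#' @param truth GroundTruth from [generateKnowledgeBase()].
#' @param path output file.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    herbMix = truth$herbMix,
    mechanisms = lapply(truth$mechanisms, function(m)
      apply(m, 1, function(r) which(r), simplify = FALSE)),
    propensity = truth$propensity), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
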