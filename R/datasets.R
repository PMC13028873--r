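## Stratified dataset recipes, strict cold-start herb splits, and the three
## negative-sampling strategies (random, degree-matched, pathway-constrained).

#' Dataset recipe: confidence band plus sampling strategy
#'
#' Balanced recipes keep, for every herb with at least `quota` qualifying
#' interactions, exactly its top-`quota` by confidence (ties broken by target
#' index ascending). Imbalanced recipes keep all qualifying interactions for
#' every herb with at least `minRequired` of them (min-for-each inclusion).
#' A global significance threshold `pThreshold` applies first.
#'
#' @param name recipe label.
#' @param minConf,maxConf confidence band edges (inclusive).
#' @param strategy "balanced" or "imbalanced".
#' @param quota fixed per-herb positive count (balanced).
#' @param minRequired minimum qualifying interactions (imbalanced).
#' @param pThreshold significance threshold, default 0.05; records with a
#'   missing p-value pass.
#' @return validated list of class "DatasetRecipe".
#' @export
datasetRecipe <- function(name, minConf, maxConf,
                          strategy = c("balanced", "imbalanced"),
                          quota = NULL, minRequired = NULL,
                          pThreshold = 0.05) {
  strategy <- match.arg(strategy)
  stopifnot(minConf <= maxConf)
  if (strategy == "balanced") stopifnot(!is.null(quota), quota >= 1)
  else stopifnot(!is.null(minRequired), minRequired >= 1)
  structure(list(name = name, minConf = minConf, maxConf = maxConf,
                 strategy = strategy, quota = quota,
                 minRequired = minRequired, pThreshold = pThreshold),
            class = "DatasetRecipe")
}

#' Build a triplet dataset from a knowledge base under a recipe
#'
#' @param kb a KnowledgeBase.
#' @param recipe a [datasetRecipe()].
#' @return a [TripletDataset-class].
#' @export
buildDataset <- function(kb, recipe) {
  stopifnot(inherits(recipe, "DatasetRecipe"))
  it <- kb@interactions
  pass <- is.na(it$p_value) | it$p_value <= recipe$pThreshold
  pass <- pass & it$confidence >= recipe$minConf &
    it$confidence <= recipe$maxConf
  it <- it[pass, , drop = FALSE]
  if (!nrow(it)) stop("empty dataset after filtering")
  counts <- table(it$herb)
  if (recipe$strategy == "balanced") {
    eligible <- as.integer(names(counts)[counts >= recipe$quota])
    it <- it[it$herb %in% eligible, , drop = FALSE]
    ## top-quota by confidence, ties by target index ascending
    o <- order(it$herb, -it$confidence, it$target)
    it <- it[o, , drop = FALSE]
    rank <- stats::ave(seq_len(nrow(it)), it$herb, FUN = seq_along)
    it <- it[rank <= recipe$quota, , drop = FALSE]
  } else {
    eligible <- as.integer(names(counts)[counts >= recipe$minRequired])
    it <- it[it$herb %in% eligible, , drop = FALSE]
    it <- it[order(it$herb, -it$confidence, it$target), , drop = FALSE]
  }
  if (!nrow(it)) stop("empty dataset after filtering")
  n <- entityCounts(kb)
  rownames(it) <- NULL
  new("TripletDataset",
      positives = it[c("herb", "target", "confidence")],
      eligibleHerbs = sort(eligible), recipe = unclass(recipe),
      nHerbs = n[["herb"]], nTargets = n[["target"]])
}

#' Cold-start split over herbs
#'
#' Herbs are shuffled by `seed` and partitioned into `nFolds` near-equal
#' groups; for fold k the test set is group k, validation the next group
#' (rotating), training the rest. The partition is over herbs, never over
#' edges: no test herb's positives are visible at training.
#'
#' @param ds a TripletDataset.
#' @param nFolds number of folds, default 5.
#' @param seed integer seed.
#' @return list of class "SplitSpec" with per-fold train/validation/test
#'   herb sets.
#' @export
coldStartSplit <- function(ds, nFolds = 5L, seed = 1L) {
  herbs <- ds@eligibleHerbs
  if (length(herbs) < nFolds) stop("fewer eligible herbs than folds")
  shuffled <- .withSeed(seed, sample(herbs))
  groups <- split(shuffled, cut(seq_along(shuffled), nFolds, labels = FALSE))
  folds <- lapply(seq_len(nFolds), function(k) {
    valIdx <- (k %% nFolds) + 1L
    list(test = sort(groups[[k]]), validation = sort(groups[[valIdx]]),
         train = sort(unlist(groups[-c(k, valIdx)], use.names = FALSE)))
  })
  structure(list(folds = folds, nFolds = nFolds, seed = seed),
            class = "SplitSpec")
}

## log2 degree bins {0}, [1,2), [2,4), [4,8), ...
.degreeBin <- function(deg) ifelse(deg == 0L, -1L, floor(log2(deg)))

#' Sample one decoy target per positive
#'
#' The decoy pool is the complement of the FULL curated interaction set of
#' the herb (all records in the knowledge base, not merely the dataset), so
#' known weak interactions are never mislabeled as decoys. Ratio is exactly
#' 1:1. Deterministic in `epochSeed`.
#'
#' Strategies: `random` draws uniformly; `degree_matched` draws from targets
#' whose PPI degree falls in the same log2 bin as the positive target
#' (nearest nonempty bin fallback); `pathway_constrained` draws from targets
#' sharing at least one KEGG annotation with the positive target, minus the
#' herb's known interactors, falling back to random with a warning when that
#' pool is empty.
#'
#' @param ds a TripletDataset.
#' @param graph a HeteroGraph (for degrees and KEGG annotations).
#' @param kb the KnowledgeBase holding the full interaction set.
#' @param herbs herbs whose positives get decoys (default: all eligible).
#' @param strategy one of "random", "degree_matched", "pathway_constrained".
#' @param epochSeed integer seed, re-drawn each training epoch.
#' @return data.frame(herb, target, decoy), one row per positive.
#' @export
sampleNegatives <- function(ds, graph, kb, herbs = ds@eligibleHerbs,
                            strategy = c("random", "degree_matched",
                                         "pathway_constrained"),
                            epochSeed = 1L) {
  strategy <- match.arg(strategy)
  pos <- ds@positives[ds@positives$herb %in% herbs, , drop = FALSE]
  nT <- ds@nTargets
  if (!nrow(pos))
    return(data.frame(herb = integer(), target = integer(),
                      decoy = integer()))
  known <- split(kb@interactions$target, kb@interactions$herb)
  deg <- if (strategy == "degree_matched") ppiDegree(graph) else NULL
  binOf <- if (!is.null(deg)) .degreeBin(deg) else NULL
  keggMates <- NULL
  if (strategy == "pathway_constrained") {
    ke <- graph@edges[["ann_KEGG"]]
    byPathway <- split(ke[, 1], ke[, 2])
    byTarget <- split(ke[, 2], ke[, 1])
    keggMates <- function(t) {
      pw <- byTarget[[as.character(t)]]
      if (is.null(pw)) return(integer())
      setdiff(unique(unlist(byPathway[as.character(pw)], use.names = FALSE)),
              t)
    }
  }
  .withSeed(epochSeed, {
    decoy <- integer(nrow(pos))
    fallbackWarned <- FALSE
    isKnown <- function(h, d) {
      mapply(function(hh, dd) dd %in% known[[as.character(hh)]], h, d)
    }
    if (strategy == "random") {
      ## vectorized rejection sampling against each herb's known set,
      ## with an exact per-positive fallback for near-saturated herbs
      decoy <- sample.int(nT, nrow(pos), replace = TRUE)
      bad <- which(isKnown(pos$herb, decoy))
      iter <- 0L
      while (length(bad) && iter < 100L) {
        decoy[bad] <- sample.int(nT, length(bad), replace = TRUE)
        bad <- bad[isKnown(pos$herb[bad], decoy[bad])]
        iter <- iter + 1L
      }
      for (i in bad) {
        pool <- setdiff(seq_len(nT), known[[as.character(pos$herb[i])]])
        if (!length(pool))
          stop("empty decoy pool for herb ", pos$herb[i],
               " (no unobserved targets)")
        decoy[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
    } else {
      for (i in seq_len(nrow(pos))) {
        h <- pos$herb[i]; t <- pos$target[i]
        excluded <- known[[as.character(h)]]
        pool <- setdiff(seq_len(nT), excluded)
        if (!length(pool))
          stop("empty decoy pool for herb ", h, " (no unobserved targets)")
        if (strategy == "degree_matched") {
          want <- binOf[t]
          cand <- pool[binOf[pool] == want]
          if (!length(cand)) {
            bins <- sort(unique(binOf[pool]))
            nearest <- bins[which.min(abs(bins - want))]
            cand <- pool[binOf[pool] == nearest]
          }
          pool <- cand
        } else if (strategy == "pathway_constrained") {
          cand <- intersect(keggMates(t), pool)
          if (length(cand)) pool <- cand
          else if (!fallbackWarned) {
            warning("pathway-constrained pool empty for some positives; ",
                    "falling back to random")
            fallbackWarned <- TRUE
          }
        }
        decoy[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
    }
    data.frame(herb = pos$herb, target = pos$target, decoy = decoy)
  })
}

#' Export a dataset with fold assignments as TSV
#'
#' @param ds a TripletDataset.
#' @param split a SplitSpec from [coldStartSplit()].
#' @param kb the source KnowledgeBase (for external identifiers).
#' @param path output file.
#' @export
writeTriplets <- function(ds, split, kb, path) {
  foldOf <- integer(ds@nHerbs)
  for (k in seq_along(split$folds)) foldOf[split$folds[[k]]$test] <- k
  p <- ds@positives
  .writeTsv(data.frame(herb_id = kb@registries$herb[p$herb],
                       target_id = kb@registries$target[p$target],
                       confidence = p$confidence,
                       fold = foldOf[p$herb]), path)
  invisible(path)
}
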