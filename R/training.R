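## Triplet training with dynamic per-epoch negative resampling, AdamW,
## early stopping on validation ROC-AUC, and the folds x seeds
## cross-validation protocol.

#' Training configuration
#'
#' @param learningRate AdamW step size.
#' @param weightDecay decoupled weight decay (applied to weight matrices and
#'   the pathway embedding table, not to biases).
#' @param maxEpochs epoch budget.
#' @param patience epochs without validation ROC-AUC improvement before
#'   stopping.
#' @param batchSize triplets per optimizer step (batches are formed from
#'   contiguous blocks of shuffled herbs so each herb's forward pass is
#'   computed once per epoch).
#' @param negativeStrategy decoy strategy for training, validation and test.
#' @param lrDecay multiplicative decay of the learning rate per epoch
#'   (1 = constant); a fast-start-then-anneal schedule stabilizes short
#'   training runs.
#' @param monitorFrom first epoch at which the early-stopping monitor may
#'   record a best model (default 1). A short burn-in avoids restoring a
#'   spuriously lucky pre-convergence epoch.
#' @param initSeed parameter initialization seed.
#' @param epochSeedBase base seed; epoch e draws decoys with seed
#'   `epochSeedBase + e`.
#' @return list of class "TrainConfig".
#' @export
trainConfig <- function(learningRate = 1e-3, weightDecay = 1e-2,
                        maxEpochs = 100L, patience = 10L, batchSize = 256L,
                        negativeStrategy = c("random", "degree_matched",
                                             "pathway_constrained"),
                        lrDecay = 1, monitorFrom = 1L, initSeed = 1L,
                        epochSeedBase = 1000L) {
  negativeStrategy <- match.arg(negativeStrategy)
  stopifnot(learningRate >= 0, weightDecay >= 0, maxEpochs >= 1,
            patience < maxEpochs, batchSize >= 1, lrDecay > 0, lrDecay <= 1,
            monitorFrom >= 1)
  structure(list(learningRate = learningRate, weightDecay = weightDecay,
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 batchSize = as.integer(batchSize),
                 negativeStrategy = negativeStrategy, lrDecay = lrDecay,
                 monitorFrom = as.integer(monitorFrom),
                 initSeed = as.integer(initSeed),
                 epochSeedBase = as.integer(epochSeedBase)),
            class = "TrainConfig")
}

#' Triplet binary cross-entropy loss
#'
#' `L = -(1/N) sum[log sigma(sActive) + log(1 - sigma(sDecoy))]`, computed
#' in numerically stabilized log-sigmoid form. Non-negative; approaches 0 as
#' active scores grow and decoy scores shrink.
#'
#' @param sActive,sDecoy raw score vectors of equal length N >= 1.
#' @return scalar loss.
#' @export
tripletLoss <- function(sActive, sDecoy) {
  if (!length(sActive) || length(sActive) != length(sDecoy))
    stop("empty batch or unequal score vectors")
  -mean(stats::plogis(sActive, log.p = TRUE) +
          stats::plogis(-sDecoy, log.p = TRUE))
}

## dL/ds for actives and decoys.
.lossGrad <- function(sActive, sDecoy) {
  N <- length(sActive)
  list(active = -(1 - .sigmoid(sActive)) / N,
       decoy = .sigmoid(sDecoy) / N)
}

## ---- AdamW -----------------------------------------------------------------

.adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.NO_DECAY <- c("bp", "b1", "b2")

.adamwStep <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (nm %in% .NO_DECAY) 0 else wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * (step + decay)
  }
  list(params = params, state = state)
}

## ---- epoch machinery -------------------------------------------------------

## Group shuffled herbs into near-equal-sized batches, targeting roughly
## batchSize triplets per batch.
.herbBatches <- function(posByHerb, herbOrder, batchSize) {
  n <- length(herbOrder)
  if (n == 0L) return(list())
  total <- sum(lengths(posByHerb[as.character(herbOrder)]))
  nGroups <- min(max(1L, as.integer(round(total / batchSize))), n)
  sizes <- rep(n %/% nGroups, nGroups)
  extra <- n %% nGroups
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(herbOrder, rep(seq_len(nGroups), sizes)))
}

## ROC-AUC (fraction) of positives vs decoys for a set of herbs.
.aucOnHerbs <- function(scoresMat, herbs, pos, decoys) {
  sPos <- sNeg <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    col <- match(pos$herb[i], herbs)
    sPos[i] <- scoresMat[pos$target[i], col]
    sNeg[i] <- scoresMat[decoys$decoy[i], col]
  }
  m <- classificationMetrics(.sigmoid(c(sPos, sNeg)),
                             rep(c(1, 0), each = nrow(pos)))
  m$rocAuc / 100
}

#' Train one cold-start fold
#'
#' Each epoch draws fresh decoys from the unobserved space (seed =
#' `epochSeedBase + epoch`), shuffles herbs, and steps AdamW on triplet
#' batches; after each epoch the validation herbs are scored (positives plus
#' one fresh decoy each) and training stops once validation ROC-AUC fails to
#' improve for `patience` epochs, restoring the best-epoch parameters. Test
#' herb positives are never touched during training.
#'
#' @param kb a KnowledgeBase.
#' @param graph the HeteroGraph (un-ablated; the model config's ablation is
#'   applied internally).
#' @param ds a TripletDataset.
#' @param split a SplitSpec from [coldStartSplit()].
#' @param fold fold number.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @return list of class "FoldResult": fold, bestEpoch, valCurve, lossCurve,
#'   testMetrics, params.
#' @export
trainFold <- function(kb, graph, ds, split, fold, modelCfg, trainCfg) {
  f <- split$folds[[fold]]
  gAbl <- .ablateGraph(graph, modelCfg)
  prop <- .makePropagator(gAbl, modelCfg)
  casc <- .cascadeOperator(kb)
  nT <- prop$nT
  cfg <- modelCfg
  cfg$seed <- trainCfg$initSeed
  params <- initParams(gAbl, ncol(kb@M_HT), cfg)
  state <- .adamwInit(params)

  pos <- ds@positives
  trainPos <- pos[pos$herb %in% f$train, , drop = FALSE]
  valPos <- pos[pos$herb %in% f$validation, , drop = FALSE]
  posByHerb <- split(seq_len(nrow(trainPos)), trainPos$herb)
  vphVal <- symptomMatrix(kb, f$validation)

  ## fixed per-fold validation decoys: a stable early-stopping monitor
  ## (the dynamic per-epoch resampling applies to the training decoys)
  valDec <- sampleNegatives(ds, graph, kb, herbs = f$validation,
                            strategy = trainCfg$negativeStrategy,
                            epochSeed = trainCfg$epochSeedBase + 50000L)

  bestAuc <- -Inf; bestParams <- params; bestEpoch <- 0L; wait <- 0L
  valCurve <- lossCurve <- numeric()

  for (epoch in seq_len(trainCfg$maxEpochs)) {
    dec <- sampleNegatives(ds, graph, kb, herbs = f$train,
                           strategy = trainCfg$negativeStrategy,
                           epochSeed = trainCfg$epochSeedBase + epoch)
    decByRow <- dec$decoy[match(
      paste(trainPos$herb, trainPos$target),
      paste(dec$herb, dec$target))]
    herbOrder <- .withSeed(trainCfg$epochSeedBase + 7L * epoch,
                           sample(f$train))
    batches <- .herbBatches(posByHerb, herbOrder, trainCfg$batchSize)
    epochLoss <- 0; nTrip <- 0L
    for (bi in seq_along(batches)) {
      herbs <- batches[[bi]]
      rows <- unlist(posByHerb[as.character(herbs)], use.names = FALSE)
      bpos <- trainPos[rows, , drop = FALSE]
      bdec <- decByRow[rows]
      vph <- symptomMatrix(kb, herbs)
      col <- match(bpos$herb, herbs)
      iPos <- (col - 1L) * nT + bpos$target
      iNeg <- (col - 1L) * nT + bdec
      fw <- .forward(prop, params, cfg, vph, casc, keepCache = TRUE,
                     scoreRows = sort(unique(c(iPos, iNeg))))
      sA <- fw$scores[iPos]; sD <- fw$scores[iNeg]
      L <- tripletLoss(sA, sD)
      if (!is.finite(L))
        stop(sprintf("non-finite loss at epoch %d batch %d", epoch, bi))
      epochLoss <- epochLoss + L * length(sA); nTrip <- nTrip + length(sA)
      lg <- .lossGrad(sA, sD)
      agg <- rowsum(c(lg$active, lg$decoy), c(iPos, iNeg))
      dScore <- numeric(nT * length(herbs))
      dScore[as.integer(rownames(agg))] <- agg
      grads <- .backward(fw, prop, params, cfg, dScore)
      lr <- trainCfg$learningRate * trainCfg$lrDecay^(epoch - 1L)
      upd <- .adamwStep(params, grads, state, lr, trainCfg$weightDecay)
      params <- upd$params; state <- upd$state
    }
    lossCurve[epoch] <- epochLoss / nTrip

    if (epoch < trainCfg$monitorFrom) {
      ## the monitor ignores burn-in epochs; skip their validation pass
      valCurve[epoch] <- NA_real_
      next
    }
    fwVal <- .forward(prop, params, cfg, vphVal, casc)
    valAuc <- .aucOnHerbs(matrix(fwVal$scores, nT), f$validation,
                          valPos, valDec)
    valCurve[epoch] <- valAuc
    if (valAuc > bestAuc) {
      bestAuc <- valAuc; bestParams <- params
      bestEpoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= trainCfg$patience) break
    }
  }

  testMetrics <- evaluateHerbs(kb, graph, ds, bestParams, cfg,
                               herbs = f$test,
                               strategy = trainCfg$negativeStrategy,
                               decoySeed = trainCfg$epochSeedBase + 90000L +
                                 fold,
                               trainPositives = NULL)
  structure(list(fold = fold, bestEpoch = bestEpoch, valCurve = valCurve,
                 lossCurve = lossCurve, testMetrics = testMetrics,
                 params = bestParams),
            class = "FoldResult")
}

#' Evaluate trained parameters on a set of herbs
#'
#' Classification metrics on the herbs' positives plus one fresh decoy per
#' positive, and ranking metrics over the candidate list (all targets minus
#' the herb's training positives; for cold-start herbs that is all targets).
#'
#' @inheritParams trainFold
#' @param params trained parameters.
#' @param cfg model config.
#' @param herbs herbs to evaluate.
#' @param strategy decoy strategy.
#' @param decoySeed seed for the evaluation decoys.
#' @param trainPositives optional data.frame(herb, target) of positives seen
#'   at training, excluded from each herb's candidate list.
#' @return named list: classification percentages, hr/ndcg at K = 10 and 20,
#'   nHerbs, plus the per-herb prediction lists (for stratified reports).
#' @export
evaluateHerbs <- function(kb, graph, ds, params, cfg, herbs, strategy,
                          decoySeed = 1L, trainPositives = NULL) {
  pos <- ds@positives[ds@positives$herb %in% herbs, , drop = FALSE]
  sc <- scoreTargets(kb, graph, params, cfg, herbs)
  dec <- sampleNegatives(ds, graph, kb, herbs = herbs, strategy = strategy,
                         epochSeed = decoySeed)
  col <- match(pos$herb, herbs)
  sPos <- sc[cbind(pos$target, col)]
  sNeg <- sc[cbind(dec$decoy, col)]
  cls <- classificationMetrics(.sigmoid(c(sPos, sNeg)),
                               rep(c(1, 0), each = nrow(pos)))
  predictions <- list()
  ranked <- relevant <- list()
  for (j in seq_along(herbs)) {
    h <- herbs[j]
    cand <- seq_len(ds@nTargets)
    if (!is.null(trainPositives))
      cand <- setdiff(cand, trainPositives$target[trainPositives$herb == h])
    rk <- rankTargets(sc[, j], cand)
    rel <- pos$target[pos$herb == h]
    if (!length(rel)) next
    ranked[[length(ranked) + 1L]] <- rk
    relevant[[length(relevant) + 1L]] <- rel
    predictions[[length(predictions) + 1L]] <-
      list(herb = h, ranked = rk, positives = rel)
  }
  rnk <- rankingMetrics(ranked, relevant)
  c(cls, as.list(rnk$hr), as.list(rnk$ndcg),
    list(nHerbs = length(herbs), predictions = predictions))
}

#' Cross-validation: folds x seeds
#'
#' Runs [trainFold()] on every fold for every initialization seed and
#' aggregates test metrics as mean and sample standard deviation (percent).
#'
#' @inheritParams trainFold
#' @param nFolds folds, default 5.
#' @param seeds initialization seeds (one run per fold per seed).
#' @param splitSeed seed of the herb partition.
#' @param folds which folds of the partition to run (default all); a subset
#'   keeps the partition identical for paired comparisons.
#' @return list(results, aggregate, split).
#' @export
runCV <- function(kb, graph, ds, modelCfg, trainCfg, nFolds = 5L,
                  seeds = 1:3, splitSeed = 1L, folds = seq_len(nFolds)) {
  split <- coldStartSplit(ds, nFolds, splitSeed)
  results <- list()
  for (fold in folds) {
    for (s in seeds) {
      tc <- trainCfg
      tc$initSeed <- as.integer(s)
      tc$epochSeedBase <- as.integer(trainCfg$epochSeedBase + 100000L * s)
      res <- trainFold(kb, graph, ds, split, fold, modelCfg, tc)
      res$seed <- s
      results[[length(results) + 1L]] <- res
    }
  }
  metricNames <- c("rocAuc", "prAuc", "accuracy", "precision", "recall",
                   "f1", "hr10", "hr20", "ndcg10", "ndcg20")
  runs <- lapply(results, function(r)
    unlist(r$testMetrics[metricNames]))
  list(results = results, aggregate = aggregateMetrics(runs), split = split)
}
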