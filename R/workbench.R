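## Orchestrated experiment recipes: knowledge-erosion curves, the ablation
## battery, negative-sampling sensitivity and hyperparameter grids. Every
## experiment fans a master seed out to stage seeds by fixed offsets, so
## runs are individually reproducible.

#' Experiment specification
#'
#' @param name experiment label.
#' @param synth a [synthConfig()] describing the knowledge base, or NULL to
#'   pass `kb`/`graph` directly to the runners.
#' @param recipe a [datasetRecipe()].
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param nFolds,seeds cross-validation layout.
#' @param masterSeed master seed; stage seeds derive from it by fixed
#'   offsets.
#' @return list of class "ExperimentSpec".
#' @export
experimentSpec <- function(name, synth = synthConfig(), recipe,
                           modelCfg = modelConfig(),
                           trainCfg = trainConfig(),
                           nFolds = 5L, seeds = 1:3, masterSeed = 1L) {
  structure(list(name = name, synth = synth, recipe = recipe,
                 modelCfg = modelCfg, trainCfg = trainCfg,
                 nFolds = as.integer(nFolds), seeds = seeds,
                 masterSeed = as.integer(masterSeed)),
            class = "ExperimentSpec")
}

.specInputs <- function(spec, kb = NULL, graph = NULL) {
  if (is.null(kb)) {
    cfgS <- spec$synth
    cfgS$seed <- spec$masterSeed
    kb <- generateKnowledgeBase(cfgS)$kb
  }
  if (is.null(graph)) graph <- buildGraph(kb)
  ds <- buildDataset(kb, spec$recipe)
  list(kb = kb, graph = graph, ds = ds)
}

#' Knowledge-erosion robustness curve
#'
#' For each erosion fraction the graph has that share of its forward edges
#' removed (supervision labels untouched), the model is retrained under the
#' cold-start protocol on the eroded graph, and mean test ROC-AUC recorded.
#' Fraction 0 reproduces the unperturbed run exactly under the same seeds.
#'
#' @param kb a KnowledgeBase.
#' @param graph the intact HeteroGraph.
#' @param ds a TripletDataset.
#' @param fractions erosion fractions, default c(0, .1, .2, .3, .4, .5).
#' @param modelCfg,trainCfg,nFolds,seeds,splitSeed protocol settings.
#' @param erosionSeed seed of the random edge removal.
#' @return data.frame(fraction, meanAuc, sdAuc).
#' @export
erosionExperiment <- function(kb, graph, ds,
                              fractions = c(0, .1, .2, .3, .4, .5),
                              modelCfg = modelConfig(),
                              trainCfg = trainConfig(),
                              nFolds = 5L, seeds = 1L, splitSeed = 1L,
                              erosionSeed = 7L) {
  rows <- lapply(fractions, function(f) {
    g <- erodeGraph(graph, f, seed = erosionSeed)
    cv <- runCV(kb, g, ds, modelCfg, trainCfg, nFolds, seeds, splitSeed)
    agg <- cv$aggregate
    data.frame(fraction = f,
               meanAuc = agg$mean[agg$metric == "rocAuc"] / 100,
               sdAuc = agg$sd[agg$metric == "rocAuc"] / 100)
  })
  do.call(rbind, rows)
}

#' Hyperparameter grid over depth and width
#'
#' One cold-start CV run per (layerO, dim1) cell; cells are independent and
#' individually seeded.
#'
#' @param spec an [experimentSpec()].
#' @param Lset outer-round depths to sweep.
#' @param dset latent widths to sweep.
#' @param kb,graph optional pre-built inputs.
#' @return data.frame(L, d, meanAuc, sdAuc).
#' @export
runGrid <- function(spec, Lset = c(2L, 4L), dset = c(8L, 16L),
                    kb = NULL, graph = NULL) {
  inp <- .specInputs(spec, kb, graph)
  cells <- expand.grid(L = Lset, d = dset)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mc <- spec$modelCfg
    mc$layerO <- as.integer(cells$L[i])
    mc$dim1 <- as.integer(cells$d[i])
    cv <- runCV(inp$kb, inp$graph, inp$ds, mc, spec$trainCfg,
                spec$nFolds, spec$seeds,
                splitSeed = spec$masterSeed + 17L)
    agg <- cv$aggregate
    data.frame(L = cells$L[i], d = cells$d[i],
               meanAuc = agg$mean[agg$metric == "rocAuc"] / 100,
               sdAuc = agg$sd[agg$metric == "rocAuc"] / 100)
  })
  do.call(rbind, rows)
}

#' Ablation battery with paired significance tests
#'
#' Runs the full model and the three ablation variants over identical folds
#' and seeds (paired design) and compares each variant's per-run ROC-AUC to
#' the full model with the paired Wilcoxon signed-rank test.
#'
#' @param spec an [experimentSpec()].
#' @param kb,graph optional pre-built inputs.
#' @return list(table, runs): the table holds mean +/- sd per metric per
#'   variant plus the Wilcoxon p-value against the full model.
#' @export
runAblations <- function(spec, kb = NULL, graph = NULL) {
  inp <- .specInputs(spec, kb, graph)
  variants <- c("none", "no_multi_ppis", "no_hgcn", "no_pathways")
  metricNames <- c("rocAuc", "prAuc", "accuracy", "precision", "recall")
  runsByVariant <- list()
  rows <- list()
  for (v in variants) {
    mc <- spec$modelCfg
    mc$ablation <- v
    cv <- runCV(inp$kb, inp$graph, inp$ds, mc, spec$trainCfg,
                spec$nFolds, spec$seeds, splitSeed = spec$masterSeed + 17L)
    perRun <- vapply(cv$results, function(r)
      unlist(r$testMetrics[metricNames]), numeric(length(metricNames)))
    runsByVariant[[v]] <- perRun
    agg <- cv$aggregate
    agg <- agg[agg$metric %in% metricNames, ]
    pw <- NA_real_
    if (v != "none") {
      full <- runsByVariant[["none"]]["rocAuc", ]
      this <- perRun["rocAuc", ]
      pw <- if (all(full == this) || length(full) < 5) NA_real_
            else wilcoxonPaired(full, this)$pValue
    }
    rows[[v]] <- data.frame(
      variant = v, t(stats::setNames(agg$mean, agg$metric)),
      wilcoxonP = pw)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       runs = runsByVariant)
}

#' Negative-sampling sensitivity
#'
#' Same folds and seeds for each strategy; the strategy applies to both
#' training and test decoy construction.
#'
#' @param spec an [experimentSpec()].
#' @param kb,graph optional pre-built inputs.
#' @return data.frame(strategy, meanAuc, sdAuc).
#' @export
runSamplingSensitivity <- function(spec, kb = NULL, graph = NULL) {
  inp <- .specInputs(spec, kb, graph)
  strategies <- c("random", "degree_matched", "pathway_constrained")
  rows <- lapply(strategies, function(st) {
    tc <- spec$trainCfg
    tc$negativeStrategy <- st
    cv <- runCV(inp$kb, inp$graph, inp$ds, spec$modelCfg, tc,
                spec$nFolds, spec$seeds, splitSeed = spec$masterSeed + 17L)
    agg <- cv$aggregate
    data.frame(strategy = st,
               meanAuc = agg$mean[agg$metric == "rocAuc"] / 100,
               sdAuc = agg$sd[agg$metric == "rocAuc"] / 100)
  })
  do.call(rbind, rows)
}
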