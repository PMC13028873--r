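## The phenotype-to-target network. A herb's binary symptom profile is
## encoded to a dense latent identity, broadcast onto targets through the
## knowledge cascade (TCM symptom -> MM symptom -> disease -> target), then
## refined by typed message passing over the PPI layers with herb-conditioned
## per-relation attention, fused with pathway context through a sigmoid
## confidence gate, and scored by a small MLP.
##
## Several herbs are processed at once: per-herb target feature matrices are
## stacked row-wise (herb b occupies rows (b-1)*nT + 1 .. b*nT), so sparse
## relation operators act as block-diagonal Kronecker products and dense
## transforms are single BLAS calls. All gradients are analytic (see
## backprop.R).

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(x) stats::plogis(x)

#' Model configuration
#'
#' Defaults are the reference architecture: target/herb latent width
#' `dim1 = 16`, pathway embedding width `dim2 = 8`, `layerI = 3` inner PPI
#' message-passing layers per outer round, `layerO = 4` outer rounds.
#'
#' @param dim1 target/herb latent width.
#' @param dim2 pathway embedding width.
#' @param layerI inner PPI layers per outer round.
#' @param layerO outer rounds.
#' @param ablation "none", "no_multi_ppis" (all PPI types collapsed to one
#'   homogeneous relation), "no_pathways" (pathway stages skipped), or
#'   "no_hgcn" (propagation bypassed; cascade features scored directly).
#' @param seed seed for parameter initialization.
#' @return list of class "ModelConfig".
#' @export
modelConfig <- function(dim1 = 16L, dim2 = 8L, layerI = 3L, layerO = 4L,
                        ablation = c("none", "no_multi_ppis", "no_pathways",
                                     "no_hgcn"),
                        seed = 1L) {
  ablation <- match.arg(ablation)
  stopifnot(dim1 >= 1, dim2 >= 1, layerI >= 1, layerO >= 1)
  structure(list(dim1 = as.integer(dim1), dim2 = as.integer(dim2),
                 layerI = as.integer(layerI), layerO = as.integer(layerO),
                 ablation = ablation, seed = as.integer(seed)),
            class = "ModelConfig")
}

## Apply the ablation's structural transform to the graph.
.ablateGraph <- function(graph, cfg) {
  switch(cfg$ablation,
         no_multi_ppis = collapsePpiTypes(graph),
         graph)
}

## ---- parameters ------------------------------------------------------------

.uinit <- function(nr, nc, fanin) {
  b <- 1 / sqrt(fanin)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

## identity-blended init for square transforms: propagation starts close to
## pure neighborhood smoothing, so the cascade relevance signal survives the
## randomly initialized layers instead of being scrambled by them
.idinit <- function(n, scale = 0.5) {
  diag(scale, n) + .uinit(n, n, n) * 0.5
}

#' Initialize model parameters
#'
#' Seeded uniform initialization scaled by fan-in; biases start at zero.
#' Per-relation transforms and attention vectors are unshared across outer
#' rounds and inner layers.
#'
#' @param graph the (possibly ablated) HeteroGraph the model will run on.
#' @param nSymptoms symptom vocabulary size `N_s`.
#' @param cfg a [modelConfig()].
#' @return flat named list of parameter arrays.
#' @export
initParams <- function(graph, nSymptoms, cfg) {
  d1 <- cfg$dim1; d2 <- cfg$dim2
  rels <- c(.ppiRelationLabels(graph), "self_loop")
  .withSeed(cfg$seed, {
    p <- list(Wp = .uinit(d1, nSymptoms, nSymptoms), bp = numeric(d1))
    for (o in seq_len(cfg$layerO)) for (i in seq_len(cfg$layerI))
      for (r in rels) {
        p[[sprintf("Wr.%d.%d.%s", o, i, r)]] <- .idinit(d1)
        p[[sprintf("attn.%d.%d.%s", o, i, r)]] <-
          stats::runif(d1, -1 / sqrt(d1), 1 / sqrt(d1))
      }
    p$Wup <- .idinit(d1)
    p$Wdown <- .idinit(d1)
    p$Wc <- .uinit(d1, d1, d1)
    p$Pemb <- .uinit(max(graph@nPathways, 1L), d2, d2)
    p$Wu <- cbind(.idinit(d1), .uinit(d1, d2, d1 + d2))
    p$Wbypass <- .idinit(d1)
    p$W1 <- .uinit(d1, d1, d1)
    p$b1 <- numeric(d1)
    p$W2 <- stats::runif(d1, -1 / sqrt(d1), 1 / sqrt(d1))
    p$b2 <- 0
    p
  })
}

## ---- graph operators -------------------------------------------------------

## Row-normalized in-neighbor averaging operator for one relation:
## A[v,u] = 1/indeg(v) for each stored edge u -> v.
.meanOperator <- function(e, nr, nc) {
  if (!nrow(e))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nr, nc)))
  cnt <- tabulate(e[, 2], nbins = nr)
  Matrix::sparseMatrix(i = e[, 2], j = e[, 1], x = 1 / cnt[e[, 2]],
                       dims = c(nr, nc))
}

## Precompute per-relation operators plus pooled pathway up/down operators.
## forB(B) returns the block-diagonal (Kronecker) versions for a batch of B
## herbs, cached per B.
.makePropagator <- function(graph, cfg) {
  nT <- graph@nTargets; nP <- graph@nPathways
  rels <- .ppiRelationLabels(graph)
  rels <- rels[vapply(rels, function(r) nrow(graph@edges[[r]]) > 0,
                      logical(1))]
  A <- lapply(rels, function(r) .meanOperator(graph@edges[[r]], nT, nT))
  names(A) <- rels
  usePathways <- cfg$ablation != "no_pathways" && nP > 0
  Bup <- Bdown <- NULL
  if (usePathways) {
    ann <- unique(do.call(rbind, lapply(.ANN_LABELS, function(l)
      if (l %in% names(graph@edges)) graph@edges[[l]] else NULL)))
    if (is.null(ann)) ann <- .emptyEdges()
    ## up: pathway row p averages member targets; down: target row v
    ## averages its annotated pathways
    Bup <- .meanOperator(ann[, c(1, 2), drop = FALSE], nP, nT)
    Bdown <- .meanOperator(ann[, c(2, 1), drop = FALSE], nT, nP)
  }
  ## only the (small) pathway pooling operators need block-diagonal
  ## expansion; PPI relations are handled per-block by the compiled kernels
  cache <- new.env(parent = emptyenv())
  forB <- function(B) {
    key <- as.character(B)
    if (!is.null(cache[[key]])) return(cache[[key]])
    I <- Matrix::Diagonal(B)
    big <- list(Bup = if (usePathways) Matrix::kronecker(I, Bup),
                Bdown = if (usePathways) Matrix::kronecker(I, Bdown))
    cache[[key]] <- big
    big
  }
  list(nT = nT, nP = nP, rels = rels, A = A, Bup = Bup, Bdown = Bdown,
       usePathways = usePathways, forB = forB)
}

## Row-normalized (by nonzero count) transposed cascade operator:
## Casc is Ns x nT; relevance R = vpheno %*% Casc.
.cascadeOperator <- function(kb) {
  rn <- function(m) {
    mt <- Matrix::t(m)
    mt@x[] <- 1
    cnt <- Matrix::rowSums(mt)
    cnt[cnt == 0] <- 1
    mt / cnt
  }
  N1 <- rn(kb@M_TM); N2 <- rn(kb@M_MD); N3 <- rn(kb@M_DT)
  Matrix::t(N3 %*% (N2 %*% N1))
}

## ---- exported single-herb building blocks ---------------------------------

#' Encode a herb's symptom profile
#'
#' `H_enc = ReLU(W_p v + b_p)`: the herb's dense pharmacological identity.
#' Defined for any binary vector including all-zeros.
#'
#' @param vpheno binary symptom vector of length `N_s`.
#' @param params parameter list from [initParams()].
#' @return numeric vector of width `dim1`.
#' @export
encodeHerb <- function(vpheno, params) {
  if (length(vpheno) != ncol(params$Wp)) stop("symptom vector length mismatch")
  .relu(as.numeric(params$Wp %*% vpheno + params$bp))
}

#' Cascade relevance of every target for a symptom profile
#'
#' Propagates the profile through the row-normalized transposed association
#' matrices: `u1 = rownorm(M_TM')v`, `u2 = rownorm(M_MD')u1`,
#' `r = rownorm(M_DT')u2`. Zero rows stay zero; targets unreachable from the
#' herb's symptoms get relevance 0.
#'
#' @param kb a KnowledgeBase.
#' @param vpheno binary symptom vector.
#' @return numeric relevance vector over targets.
#' @export
cascadeRelevance <- function(kb, vpheno) {
  as.numeric(vpheno %*% .cascadeOperator(kb))
}

#' Cascade initialization of target features
#'
#' Every target receives the herb identity scaled by its cascade relevance:
#' `H_target(0)[v] = r[v] * H_enc`.
#'
#' @param kb a KnowledgeBase.
#' @param vpheno binary symptom vector.
#' @param Henc encoded herb identity from [encodeHerb()].
#' @return matrix `nTargets x dim1`.
#' @export
cascadeInit <- function(kb, vpheno, Henc) {
  r <- cascadeRelevance(kb, vpheno)
  outer(r, Henc)
}

#' Score a fused embedding
#'
#' `s = W2 ReLU(W1 e + b1) + b2`, `P = sigmoid(s)`.
#'
#' @param e fused embedding vector of width `dim1`.
#' @param params parameter list.
#' @return list(score, probability).
#' @export
scoreEmbedding <- function(e, params) {
  s <- sum(params$W2 * .relu(as.numeric(params$W1 %*% e + params$b1))) +
    params$b2
  list(score = s, probability = .sigmoid(s))
}

## ---- batched forward -------------------------------------------------------

## vph: B x Ns binary matrix; casc: Ns x nT cascade operator.
## Returns scores (stacked length nT*B) and, when keepCache, everything the
## backward pass needs.
.forward <- function(prop, params, cfg, vph, casc,
                     keepCache = FALSE, trace = FALSE, scoreRows = NULL) {
  B <- nrow(vph); nT <- prop$nT; d1 <- cfg$dim1; d2 <- cfg$dim2
  preE <- vph %*% t(params$Wp) + rep(params$bp, each = B)
  Henc <- .relu(preE)                              # B x d1
  R <- as.matrix(vph %*% casc)                     # B x nT
  ## per-herb max-normalization of the cascade relevance: scale-free, keeps
  ## the relative relevance ranking but prevents vanishing activations when
  ## the target space is large
  rmax <- apply(R, 1, max)
  R <- R / ifelse(rmax > 0, rmax, 1)
  rvec <- as.vector(t(R))                          # stacked (b-major)
  idxB <- rep(seq_len(B), each = nT)
  H0 <- Henc[idxB, , drop = FALSE] * rvec          # (nT*B) x d1

  if (cfg$ablation == "no_hgcn") {
    e <- H0 %*% t(params$Wbypass)
    if (is.null(scoreRows)) {
      sc <- .scoreRows(e, params)
      scores <- sc$s
    } else {
      sc <- .scoreRows(e[scoreRows, , drop = FALSE], params)
      scores <- numeric(nT * B)
      scores[scoreRows] <- sc$s
    }
    return(list(scores = scores, e = e, Henc = Henc, R = R, H0 = H0,
                B = B, nT = nT, vph = vph, preA1 = sc$preA1,
                scoreRows = scoreRows))
  }

  big <- prop$forB(B)
  Hcache <- if (keepCache) vector("list", cfg$layerO)
  Fpcache <- Fpwcache <- Ffcache <- Ccache <-
    if (keepCache) vector("list", cfg$layerO)
  alphas <- list()
  traceRounds <- if (trace) vector("list", cfg$layerO)

  PembBar <- NULL
  if (prop$usePathways) {
    PembBar1 <- as.matrix(prop$Bdown %*% params$Pemb)   # nT x d2
    PembBar <- PembBar1[rep(seq_len(nT), B), , drop = FALSE]
  }

  allRels <- c(prop$rels, "self_loop")
  nR <- length(allRels)
  Alist <- c(prop$A[prop$rels], list(NULL))
  ## herb-conditioned per-relation attention scalars for every inner step
  alphaO <- lapply(seq_len(cfg$layerO), function(o) {
    m <- matrix(0, B, nR * cfg$layerI)
    for (i in seq_len(cfg$layerI)) for (k in seq_len(nR)) {
      key <- sprintf("attn.%d.%d.%s", o, i, allRels[k])
      a <- .sigmoid(Henc %*% params[[key]])
      m[, (i - 1L) * nR + k] <- a
      alphas[[sprintf("%d.%d.%s", o, i, allRels[k])]] <<- as.numeric(a)
    }
    m
  })
  ## all relations' transforms stacked per inner step (stripe r = W_r)
  Wstacks <- lapply(seq_len(cfg$layerO), function(o)
    lapply(seq_len(cfg$layerI), function(i)
      do.call(rbind, lapply(allRels, function(r)
        params[[sprintf("Wr.%d.%d.%s", o, i, r)]]))))

  Pcache <- if (keepCache) vector("list", cfg$layerO)
  H <- H0
  for (o in seq_len(cfg$layerO)) {
    inner <- .innerForwardCpp(t(H), Wstacks[[o]], Alist, alphaO[[o]],
                              nT, B, keepCache)
    if (keepCache) {
      Hcache[[o]] <- inner$states                 # transposed layout
      Pcache[[o]] <- inner$P
    }
    H <- t(inner$states[[cfg$layerI + 1L]])
    Ft <- H
    if (prop$usePathways) {
      Mt <- as.matrix(big$Bup %*% Ft)
      Fpw <- .relu(Mt %*% t(params$Wup))
      Fp <- as.matrix(big$Bdown %*% Fpw) %*% t(params$Wdown)
      C <- .sigmoid(Fp %*% params$Wc)
      Ff <- C * Ft + Fp
      if (keepCache) {
        Fpcache[[o]] <- Fp; Fpwcache[[o]] <- Fpw; Ccache[[o]] <- C
      }
      if (trace) traceRounds[[o]] <- list(F_target = Ft, F_pathway = Fpw,
                                          F_pathway_down = Fp, C = C,
                                          F_fused = Ff)
    } else {
      Ff <- Ft
      if (trace) traceRounds[[o]] <- list(F_target = Ft, F_fused = Ff)
    }
    if (keepCache) Ffcache[[o]] <- Ff
    if (o < cfg$layerO) {
      cat2 <- if (prop$usePathways) PembBar
              else matrix(0, nrow(Ff), d2)
      H <- cbind(Ff, cat2) %*% t(params$Wu)
    } else {
      e <- Ff
    }
  }
  if (is.null(scoreRows)) {
    sc <- .scoreRows(e, params)
    scores <- sc$s
  } else {
    sc <- .scoreRows(e[scoreRows, , drop = FALSE], params)
    scores <- numeric(nT * B)
    scores[scoreRows] <- sc$s
  }
  list(scores = scores, e = e, preA1 = sc$preA1, scoreRows = scoreRows,
       Henc = Henc, R = R, H0 = H0,
       B = B, nT = nT, vph = vph, alphas = alphas, alphaO = alphaO,
       Wstacks = Wstacks, Alist = Alist, allRels = allRels,
       Hcache = Hcache, Pcache = Pcache, Fpcache = Fpcache,
       Fpwcache = Fpwcache, Ffcache = Ffcache, Ccache = Ccache,
       PembBar = PembBar,
       trace = if (trace) traceRounds)
}

.scoreRows <- function(e, params) {
  preA1 <- e %*% t(params$W1) + rep(params$b1, each = nrow(e))
  s <- as.numeric(.relu(preA1) %*% params$W2) + params$b2
  list(s = s, preA1 = preA1)
}

## ---- user-facing forward wrappers -----------------------------------------

#' Score all targets for a set of herbs
#'
#' Runs the full forward pass (encode, cascade, propagate, score) for each
#' herb's symptom profile. Purely inductive: depends only on the symptom
#' profiles, the graph and shared parameters, never on the herbs' own
#' interaction records.
#'
#' @param kb a KnowledgeBase.
#' @param graph a HeteroGraph (un-ablated; the config's ablation is applied
#'   internally).
#' @param params parameters from [initParams()] or a trained fold.
#' @param cfg the [modelConfig()] the parameters were created under.
#' @param herbs integer herb indices.
#' @return matrix `nTargets x length(herbs)` of raw scores (apply
#'   `plogis` for probabilities).
#' @export
scoreTargets <- function(kb, graph, params, cfg, herbs) {
  g <- .ablateGraph(graph, cfg)
  prop <- .makePropagator(g, cfg)
  casc <- .cascadeOperator(kb)
  vph <- symptomMatrix(kb, herbs)
  fw <- .forward(prop, params, cfg, vph, casc)
  matrix(fw$scores, prop$nT, length(herbs),
         dimnames = list(NULL, as.character(herbs)))
}

#' Forward pass for one triplet
#'
#' A single shared forward pass scores both the active and the decoy target.
#'
#' @param herb herb index.
#' @param tPos,tNeg active and decoy target indices.
#' @inheritParams scoreTargets
#' @return named numeric vector c(sPos, sNeg) of raw scores.
#' @export
forwardTriplet <- function(herb, tPos, tNeg, kb, graph, params, cfg) {
  s <- scoreTargets(kb, graph, params, cfg, herb)
  c(sPos = s[tPos, 1], sNeg = s[tNeg, 1])
}

#' Record a full forward trace for one herb
#'
#' @inheritParams scoreTargets
#' @param herb herb index.
#' @return list with Henc, cascade relevance, per-layer attention scalars,
#'   per-round features, gates and final scores.
#' @export
forwardTrace <- function(kb, graph, params, cfg, herb) {
  g <- .ablateGraph(graph, cfg)
  prop <- .makePropagator(g, cfg)
  casc <- .cascadeOperator(kb)
  vph <- symptomMatrix(kb, herb)
  fw <- .forward(prop, params, cfg, vph, casc, trace = TRUE)
  list(Henc = fw$Henc[1, ], relevance = fw$R[1, ], alphas = fw$alphas,
       rounds = fw$trace, scores = fw$scores)
}

#' Pathway attribution for one predicted interaction
#'
#' Leave-one-pathway-out: for each pathway annotated to the target, its
#' annotation edges are removed, the forward pass recomputed, and the drop
#' in the target's score recorded. Drops are clamped at zero and
#' max-normalized to [0,1], sorted descending.
#'
#' @inheritParams scoreTargets
#' @param herb herb index.
#' @param target target index.
#' @return data.frame(pathway, contribution), sorted by contribution.
#' @export
attributePathways <- function(kb, graph, params, cfg, herb, target) {
  if (cfg$ablation == "no_pathways") {
    warning("pathway stage disabled under the no_pathways ablation")
    return(data.frame(pathway = integer(), contribution = numeric()))
  }
  ann <- kb@annotations
  pws <- sort(unique(ann$pathway[ann$target == target]))
  if (!length(pws))
    return(data.frame(pathway = integer(), contribution = numeric()))
  s0 <- scoreTargets(kb, graph, params, cfg, herb)[target, 1]
  drops <- vapply(pws, function(p) {
    g2 <- graph
    for (l in c(.ANN_LABELS)) {
      e <- g2@edges[[l]]
      keep <- !(e[, 1] == target & e[, 2] == p)
      g2@edges[[l]] <- e[keep, , drop = FALSE]
      inv <- paste0("inv_", l)
      ei <- g2@edges[[inv]]
      g2@edges[[inv]] <- ei[!(ei[, 1] == p & ei[, 2] == target), ,
                            drop = FALSE]
    }
    s0 - scoreTargets(kb, g2, params, cfg, herb)[target, 1]
  }, numeric(1))
  contrib <- pmax(drops, 0)
  if (max(contrib) > 0) contrib <- contrib / max(contrib)
  out <- data.frame(pathway = pws, contribution = contrib)
  out[order(-out$contribution, out$pathway), , drop = FALSE]
}
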