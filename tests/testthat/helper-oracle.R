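## An independent, loop-based dense re-implementation of the forward pass
## used as the oracle for the vectorized implementation.
denseOracleForward <- function(kb, graph, params, cfg, herb) {
  nT <- graph@nTargets; nP <- graph@nPathways
  d1 <- cfg$dim1; d2 <- cfg$dim2
  v <- symptomVector(kb, herb)
  Henc <- pmax(as.numeric(params$Wp %*% v + params$bp), 0)
  ## cascade: row-normalized transposed hops over binarized matrices
  hop <- function(M, x) {
    Mt <- t(as.matrix(M) != 0) * 1
    cnt <- rowSums(Mt)
    out <- as.numeric(Mt %*% x)
    ifelse(cnt > 0, out / cnt, 0)
  }
  r <- hop(kb@M_DT, hop(kb@M_MD, hop(kb@M_TM, v)))
  if (max(r) > 0) r <- r / max(r)
  H <- outer(r, Henc)
  if (cfg$ablation == "no_hgcn") {
    e <- H %*% t(params$Wbypass)
  } else {
    rels <- c(intersect(names(graph@edges),
                        c("binary", "complexes", "kinase", "literature",
                          "metabolic", "regulatory", "signaling",
                          paste0("inv_", c("kinase", "metabolic",
                                           "regulatory", "signaling")),
                          "ppi")), "self_loop")
    rels <- rels[vapply(rels, function(rr)
      rr == "self_loop" || nrow(graph@edges[[rr]]) > 0, logical(1))]
    annPairs <- unique(do.call(rbind, lapply(
      paste0("ann_", c("KEGG", "GO_BP", "GO_MF", "GO_CC")),
      function(l) graph@edges[[l]])))
    pembBar <- matrix(0, nT, d2)
    for (t in seq_len(nT)) {
      pws <- annPairs[annPairs[, 1] == t, 2]
      if (length(pws))
        pembBar[t, ] <- colMeans(params$Pemb[pws, , drop = FALSE])
    }
    usePw <- cfg$ablation != "no_pathways"
    for (o in seq_len(cfg$layerO)) {
      for (i in seq_len(cfg$layerI)) {
        S <- matrix(0, nT, d1)
        for (rel in rels) {
          a <- plogis(sum(params[[sprintf("attn.%d.%d.%s", o, i, rel)]] *
                            Henc))
          W <- params[[sprintf("Wr.%d.%d.%s", o, i, rel)]]
          for (t in seq_len(nT)) {
            nb <- if (rel == "self_loop") t
                  else {
                    e <- graph@edges[[rel]]
                    e[e[, 2] == t, 1]
                  }
            if (length(nb))
              S[t, ] <- S[t, ] + a *
                as.numeric(W %*% colMeans(H[nb, , drop = FALSE]))
          }
        }
        H <- pmax(S, 0)
      }
      Ft <- H
      if (usePw) {
        Fpw <- matrix(0, nP, d1)
        for (p in seq_len(nP)) {
          mem <- annPairs[annPairs[, 2] == p, 1]
          if (length(mem))
            Fpw[p, ] <- pmax(as.numeric(
              params$Wup %*% colMeans(Ft[mem, , drop = FALSE])), 0)
        }
        Fp <- matrix(0, nT, d1)
        for (t in seq_len(nT)) {
          pws <- annPairs[annPairs[, 1] == t, 2]
          if (length(pws))
            Fp[t, ] <- as.numeric(
              params$Wdown %*% colMeans(Fpw[pws, , drop = FALSE]))
        }
        C <- plogis(Fp %*% params$Wc)
        Ff <- C * Ft + Fp
      } else Ff <- Ft
      if (o < cfg$layerO) {
        cat2 <- if (usePw) pembBar else matrix(0, nT, d2)
        H <- cbind(Ff, cat2) %*% t(params$Wu)
      } else e <- Ff
    }
  }
  apply(e, 1, function(row)
    sum(params$W2 * pmax(as.numeric(params$W1 %*% row + params$b1), 0)) +
      params$b2)
}
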