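## Analytic gradients for the batched forward pass in model.R. The layout
## mirrors the forward exactly: stacked (nT*B) x dim1 feature matrices,
## block-diagonal sparse operators, flat named parameter list. Verified
## against numerical differentiation in the test suite.

## dScore: length nT*B vector of dL/ds at every stacked row (mostly zero).
.backward <- function(fw, prop, params, cfg, dScore) {
  d1 <- cfg$dim1; d2 <- cfg$dim2
  nT <- fw$nT; B <- fw$B
  idxB <- rep(seq_len(B), each = nT)
  g <- list()
  add <- function(nm, val) {
    g[[nm]] <<- if (is.null(g[[nm]])) val else g[[nm]] + val
  }

  ## scorer (restricted to the scored rows when the forward pass was)
  sr <- fw$scoreRows
  dScoreS <- if (is.null(sr)) dScore else dScore[sr]
  eS <- if (is.null(sr)) fw$e else fw$e[sr, , drop = FALSE]
  mask1 <- fw$preA1 > 0
  A1 <- .relu(fw$preA1)
  add("W2", as.numeric(crossprod(A1, dScoreS)))
  add("b2", sum(dScoreS))
  da1 <- (dScoreS %o% params$W2) * mask1
  add("W1", crossprod(da1, eS))
  add("b1", colSums(da1))
  deS <- da1 %*% params$W1
  de <- if (is.null(sr)) deS else {
    m <- matrix(0, nT * B, d1)
    m[sr, ] <- deS
    m
  }

  rvec <- as.vector(t(fw$R))
  dHenc <- matrix(0, B, d1)

  if (cfg$ablation == "no_hgcn") {
    add("Wbypass", crossprod(de, fw$H0))
    dH0 <- de %*% params$Wbypass
    dHenc <- dHenc + rowsum(dH0 * rvec, idxB)
  } else {
    big <- prop$forB(B)
    dPembBar <- if (prop$usePathways) matrix(0, nT * B, d2)
    Gf <- de
    for (o in seq(cfg$layerO, 1L)) {
      Ft <- t(fw$Hcache[[o]][[cfg$layerI + 1L]])
      if (prop$usePathways) {
        Fp <- fw$Fpcache[[o]]; Fpw <- fw$Fpwcache[[o]]
        C <- fw$Ccache[[o]]
        dFt <- Gf * C
        dpreC <- (Gf * Ft) * C * (1 - C)
        dFp <- Gf + dpreC %*% t(params$Wc)
        add("Wc", crossprod(Fp, dpreC))
        Md <- as.matrix(big$Bdown %*% Fpw)
        add("Wdown", crossprod(dFp, Md))
        dMd <- dFp %*% params$Wdown
        dFpw <- as.matrix(Matrix::crossprod(big$Bdown, dMd))
        dZp <- dFpw * (Fpw > 0)
        Mt <- as.matrix(big$Bup %*% Ft)
        add("Wup", crossprod(dZp, Mt))
        dMt <- dZp %*% params$Wup
        dFt <- dFt + as.matrix(Matrix::crossprod(big$Bup, dMt))
      } else {
        dFt <- Gf
      }
      ## inner PPI layers: compiled backward kernel over all steps
      allRels <- fw$allRels
      nR <- length(allRels)
      res <- .innerBackwardCpp(t(dFt), fw$Hcache[[o]], fw$Pcache[[o]],
                               fw$Wstacks[[o]], fw$Alist, fw$alphaO[[o]],
                               nT, B)
      for (i in seq_len(cfg$layerI)) {
        for (k in seq_len(nR)) {
          r <- allRels[k]
          stripe <- (k - 1L) * d1 + seq_len(d1)
          add(sprintf("Wr.%d.%d.%s", o, i, r),
              res$gW[[i]][stripe, , drop = FALSE])
          a <- fw$alphaO[[o]][, (i - 1L) * nR + k]
          dpreA <- res$dAlpha[, (i - 1L) * nR + k] * a * (1 - a)
          add(sprintf("attn.%d.%d.%s", o, i, r),
              as.numeric(crossprod(fw$Henc, dpreA)))
          dHenc <- dHenc + dpreA %o%
            params[[sprintf("attn.%d.%d.%s", o, i, r)]]
        }
      }
      dH <- t(res$dH)
      if (o > 1L) {
        cat2 <- if (prop$usePathways) fw$PembBar
                else matrix(0, nT * B, d2)
        concatIn <- cbind(fw$Ffcache[[o - 1L]], cat2)
        add("Wu", crossprod(dH, concatIn))
        dConcat <- dH %*% params$Wu
        Gf <- dConcat[, seq_len(d1), drop = FALSE]
        if (prop$usePathways)
          dPembBar <- dPembBar +
            dConcat[, d1 + seq_len(d2), drop = FALSE]
      } else {
        dHenc <- dHenc + rowsum(dH * rvec, idxB)
      }
    }
    if (prop$usePathways && any(dPembBar != 0)) {
      dPembBar1 <- rowsum(dPembBar, rep(seq_len(nT), B))
      add("Pemb", as.matrix(Matrix::crossprod(prop$Bdown, dPembBar1)))
    }
  }

  ## encoder
  dpreE <- dHenc * (fw$Henc > 0)
  add("Wp", crossprod(dpreE, fw$vph))
  add("bp", colSums(dpreE))
  g
}
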