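## Metrics and analysis protocols: classification and ranking metrics, the
## degree baseline, stratified reports, paired signed-rank testing and
## pathway over-representation.

#' Classification metrics at a fixed threshold
#'
#' ROC-AUC by the rank statistic with tie-midranking; PR-AUC by the
#' precision-recall step integral over grouped thresholds; accuracy,
#' precision, recall and F1 at `threshold`. All reported as percentages.
#' With a single class present the AUCs are `NA` (absent, not 50).
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 vector.
#' @param threshold decision threshold on the probability, default 0.5.
#' @return named list of percentages plus `nPairs`.
#' @export
classificationMetrics <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  rocAuc <- prAuc <- NA_real_
  if (n1 > 0 && n0 > 0) {
    rk <- rank(probs)                       # midranks under ties
    rocAuc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ## step integral over distinct thresholds, descending
    o <- order(-probs)
    p <- probs[o]; y <- labels[o]
    grp <- cumsum(!duplicated(p))
    tp <- cumsum(y); fp <- cumsum(1 - y)
    last <- !duplicated(grp, fromLast = TRUE)
    tpg <- tp[last]; fpg <- fp[last]
    prec <- tpg / (tpg + fpg)
    rec <- tpg / n1
    prAuc <- sum(diff(c(0, rec)) * prec)
  }
  pred <- as.numeric(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  accuracy <- mean(pred == labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(rocAuc = 100 * rocAuc, prAuc = 100 * prAuc,
       accuracy = 100 * accuracy, precision = 100 * precision,
       recall = 100 * recall, f1 = 100 * f1,
       nPairs = length(labels))
}

#' Top-K ranking metrics
#'
#' Per herb, `HR@K = |relevant in top K| / min(K, |relevant|)` (the
#' proportion convention; set `binaryHit = TRUE` for the binary top-K hit
#' convention) and `NDCG@K = DCG@K / IDCG@K` with unit gain and
#' `1/log2(rank+1)` discount. Macro-averaged over herbs. Ranked lists must
#' already be deterministic (score ties broken by target index).
#'
#' @param ranked list of ranked target vectors, one per herb.
#' @param relevant list of relevant (held-out positive) target vectors.
#' @param K cutoffs, default c(10, 20).
#' @param binaryHit use the binary hit convention for HR.
#' @return named list `hr` and `ndcg`, each a named vector over K.
#' @export
rankingMetrics <- function(ranked, relevant, K = c(10, 20),
                           binaryHit = FALSE) {
  stopifnot(length(ranked) == length(relevant))
  if (any(vapply(relevant, length, integer(1)) == 0))
    stop("every herb needs at least one relevant target")
  hr <- ndcg <- matrix(0, length(ranked), length(K))
  for (h in seq_along(ranked)) {
    rk <- match(relevant[[h]], ranked[[h]])   # ranks of relevant targets
    for (j in seq_along(K)) {
      k <- K[j]
      nrel <- length(relevant[[h]])
      hit <- sum(!is.na(rk) & rk <= k)
      hr[h, j] <- if (binaryHit) as.numeric(hit > 0)
                  else hit / min(k, nrel)
      dcg <- sum(1 / log2(rk[!is.na(rk) & rk <= k] + 1))
      idcg <- sum(1 / log2(seq_len(min(k, nrel)) + 1))
      ndcg[h, j] <- dcg / idcg
    }
  }
  list(hr = stats::setNames(colMeans(hr), paste0("hr", K)),
       ndcg = stats::setNames(colMeans(ndcg), paste0("ndcg", K)))
}

#' Rank candidate targets by score, ties broken by target index
#'
#' @param scores numeric score vector over all targets.
#' @param candidates candidate target indices (default: all).
#' @return candidate indices in descending score order.
#' @export
rankTargets <- function(scores, candidates = seq_along(scores)) {
  if (!length(candidates)) stop("empty candidate list")
  candidates[order(-scores[candidates], candidates)]
}

#' Degree baseline scores
#'
#' The herb-independent null model: every target scored by its number of
#' distinct PPI partners.
#'
#' @param graph a HeteroGraph.
#' @return numeric score vector over targets.
#' @export
degreeBaseline <- function(graph) {
  as.numeric(ppiDegree(graph))
}

#' Stratified evaluation by target degree or pathway-annotation depth
#'
#' Partitions held-out positives by their target's stratum — degree strata
#' k<10 (Tail), 10<=k<=50 (Medium), k>50 (High); pathway strata k_path<3
#' (Sparse), 3<=k_path<=20 (Moderate), k_path>20 (Rich) — and reports the
#' per-stratum Recall@20 (fraction of stratum positives appearing in their
#' herb's top 20).
#'
#' @param predictions list of per-herb entries, each with `ranked` (ranked
#'   candidate vector) and `positives` (held-out positive targets).
#' @param graph a HeteroGraph (for degrees).
#' @param annotations annotation data.frame (for pathway counts).
#' @param mode "degree" or "pathway".
#' @return data.frame(stratum, n, recall20); empty strata appear with n = 0.
#' @export
stratifiedEval <- function(predictions, graph, annotations,
                           mode = c("degree", "pathway")) {
  mode <- match.arg(mode)
  if (mode == "degree") {
    k <- ppiDegree(graph)
    strata <- cut(k, c(-Inf, 9.5, 50.5, Inf),
                  labels = c("tail_k<10", "medium_10<=k<=50", "high_k>50"))
  } else {
    kp <- integer(graph@nTargets)
    if (nrow(annotations)) {
      cnt <- tapply(annotations$pathway, annotations$target,
                    function(x) length(unique(x)))
      kp[as.integer(names(cnt))] <- as.integer(cnt)
    }
    strata <- cut(kp, c(-Inf, 2.5, 20.5, Inf),
                  labels = c("sparse_k<3", "moderate_3<=k<=20", "rich_k>20"))
  }
  lev <- levels(strata)
  hits <- total <- stats::setNames(numeric(length(lev)), lev)
  for (pr in predictions) {
    top20 <- utils::head(pr$ranked, 20)
    for (t in pr$positives) {
      s <- as.character(strata[t])
      total[s] <- total[s] + 1
      hits[s] <- hits[s] + (t %in% top20)
    }
  }
  data.frame(stratum = lev, n = as.integer(total),
             recall20 = ifelse(total > 0, hits / total, NA_real_))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided, with zero differences dropped and ties midranked. The null
#' distribution is exact for n <= 25 (computed by convolution over the
#' doubled midranks, which handles ties exactly); beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b paired metric series of equal length >= 5.
#' @return list(statistic = W, pValue).
#' @export
wilcoxonPaired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))          # doubled midranks are integers
    maxW <- sum(r2)
    dist <- numeric(maxW + 1L); dist[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(maxW + 1L - ri)])
      dist <- (dist + shifted) / 2
    }
    W2 <- as.integer(round(2 * W))
    pLe <- sum(dist[seq_len(W2 + 1L)])
    pGe <- sum(dist[seq(W2 + 1L, maxW + 1L)])
    p <- min(1, 2 * min(pLe, pGe))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = W, pValue = p)
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric tail per pathway over a background universe,
#' with Benjamini-Hochberg adjustment across tested pathways.
#'
#' @param predicted predicted top target indices.
#' @param annotations annotation data.frame (target, pathway, type).
#' @param background background target universe (must contain `predicted`).
#' @return data.frame(pathway, overlap, size, odds, p, q) sorted by q.
#' @export
enrichment <- function(predicted, annotations, background) {
  if (!length(predicted)) stop("empty prediction set")
  if (!all(predicted %in% background))
    stop("background must contain the predicted set")
  ann <- annotations[annotations$target %in% background, , drop = FALSE]
  N <- length(unique(background)); nPred <- length(unique(predicted))
  out <- lapply(split(ann$target, ann$pathway), unique)
  res <- do.call(rbind, lapply(names(out), function(pw) {
    members <- out[[pw]]
    K <- length(members)
    x <- length(intersect(predicted, members))
    p <- stats::phyper(x - 1, K, N - K, nPred, lower.tail = FALSE)
    odds <- (x / max(nPred - x, 1)) / (max(K - x, 1) / max(N - K - nPred + x, 1))
    data.frame(pathway = as.integer(pw), overlap = x, size = K,
               odds = odds, p = p)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$q, res$p, res$pathway), , drop = FALSE]
}

#' Aggregate per-run metric vectors as mean and sample standard deviation
#'
#' @param runs list of named numeric vectors (one per fold x seed run).
#' @return data.frame(metric, mean, sd).
#' @export
aggregateMetrics <- function(runs) {
  m <- do.call(rbind, lapply(runs, unlist))
  data.frame(metric = colnames(m),
             mean = colMeans(m, na.rm = TRUE),
             sd = apply(m, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}
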