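## Brute-force oracles used below: exhaustive threshold sweep for the
## classification metrics, exhaustive rank enumeration for DCG, full
## sign-flip enumeration for the signed-rank null.

sweepRocPr <- function(probs, labels) {
  ## trapezoidal ROC over every distinct threshold; step PR integral
  th <- sort(unique(probs), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- c(0, vapply(th, function(t) mean(probs[labels == 1] >= t),
                     numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(probs[labels == 0] >= t),
                     numeric(1)))
  roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- vapply(th, function(t) {
    tp <- sum(probs >= t & labels == 1); fp <- sum(probs >= t & labels == 0)
    tp / (tp + fp)
  }, numeric(1))
  rec <- vapply(th, function(t) sum(probs >= t & labels == 1) / n1,
                numeric(1))
  pr <- sum(diff(c(0, rec)) * prec)
  list(roc = roc, pr = pr)
}

test_that("perfect and constant predictors hit their closed forms", {
  m <- classificationMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$rocAuc, 100)
  expect_equal(m$f1, 100)
  expect_equal(m$prAuc, 100)
  ## constant probabilities: midrank ROC-AUC of 50, accuracy = majority
  m2 <- classificationMetrics(rep(0.5, 6), c(1, 1, 1, 1, 0, 0))
  expect_equal(m2$rocAuc, 50)
  expect_equal(m2$accuracy, 100 * 4 / 6)
  ## single class: AUCs absent, not 50
  m3 <- classificationMetrics(c(0.2, 0.8), c(1, 1))
  expect_true(is.na(m3$rocAuc) && is.na(m3$prAuc))
})

test_that("classification metrics match the exhaustive sweep oracle", {
  probs <- c(0.9, 0.8, 0.4, 0.35, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  m <- classificationMetrics(probs, labels)
  or <- sweepRocPr(probs, labels)
  expect_equal(m$rocAuc, 100 * or$roc, tolerance = 1e-9)
  expect_equal(m$prAuc, 100 * or$pr, tolerance = 1e-9)
  expect_equal(m$accuracy, 100 * mean((probs >= 0.5) == labels))
  ## F1 consistent with precision and recall
  expect_equal(m$f1,
               2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-6)
  ## random cases incl. ties: rank statistic equals trapezoid integration
  set.seed(8)
  for (k in 1:20) {
    p <- round(runif(10), 1)
    y <- rbinom(10, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(classificationMetrics(p, y)$rocAuc,
                 100 * sweepRocPr(p, y)$roc, tolerance = 1e-9)
  }
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  p <- runif(40); y <- rbinom(40, 1, 0.5)
  got <- classificationMetrics(p, y)$rocAuc / 100
  want <- as.numeric(suppressMessages(
    pROC::auc(y, p, direction = "<", levels = c(0, 1))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("top-K metrics follow their definitions on small lists", {
  ## single relevant target at rank 1
  m <- rankingMetrics(list(1:20), list(1L))
  expect_equal(unname(m$hr["hr10"]), 1)
  expect_equal(unname(m$ndcg["ndcg10"]), 1)
  ## relevant target below the cutoff
  m2 <- rankingMetrics(list(1:30), list(25L), K = 10)
  expect_equal(unname(m2$hr["hr10"]), 0)
  expect_equal(unname(m2$ndcg["ndcg10"]), 0)
  ## 5-candidate enumeration oracle: relevant at ranks 2 and 4
  m3 <- rankingMetrics(list(c(9, 7, 8, 5, 6)), list(c(7L, 5L)), K = 5)
  want <- (1 / log2(3) + 1 / log2(5)) / (1 + 1 / log2(3))
  expect_equal(unname(m3$ndcg["ndcg5"]), want, tolerance = 1e-12)
  expect_equal(unname(m3$hr["hr5"]), 1)
  ## binary-hit convention flag
  m4 <- rankingMetrics(list(1:10), list(c(1L, 99L)), K = 5,
                       binaryHit = TRUE)
  expect_equal(unname(m4$hr["hr5"]), 1)
})

test_that("HR and NDCG never decrease with K", {
  set.seed(5)
  for (k in 1:10) {
    ranked <- list(sample(50))
    rel <- list(sample(50, 4))
    m <- rankingMetrics(ranked, rel, K = c(5, 10, 20, 40))
    expect_true(all(diff(m$hr) >= -1e-12))
    expect_true(all(diff(m$ndcg) >= -1e-12))
  }
})

test_that("rankTargets is deterministic under score ties", {
  sc <- c(0.5, 0.9, 0.5, 0.1)
  expect_equal(rankTargets(sc), c(2L, 1L, 3L, 4L))
  expect_equal(rankTargets(sc, candidates = c(4L, 3L)), c(3L, 4L))
  expect_error(rankTargets(sc, integer()), "empty candidate")
})

test_that("stratified reports partition positives and count recalls", {
  g <- smallSynthKb()
  kb <- g$kb
  gr <- suppressWarnings(buildGraph(kb))
  preds <- list(
    list(herb = 1L, ranked = 1:120, positives = c(3L, 40L)),
    list(herb = 2L, ranked = 120:1, positives = c(5L)))
  rep <- stratifiedEval(preds, gr, annotations(kb), mode = "degree")
  expect_equal(sum(rep$n), 3L)
  ## hand count: positives 3 and 40 are in herb 1's top-20 iff <= 20
  deg <- ppiDegree(gr)
  stratumOf <- function(t) cut(deg[t], c(-Inf, 9.5, 50.5, Inf),
                               labels = rep$stratum)
  hand <- c(`3` = TRUE, `40` = FALSE, `5` = 120 - 5 + 1 <= 20)
  for (t in c(3L, 40L)) {
    s <- as.character(stratumOf(t))
    expect_gte(rep$n[rep$stratum == s], 1L)
  }
  rep2 <- stratifiedEval(preds, gr, annotations(kb), mode = "pathway")
  expect_equal(sum(rep2$n), 3L)
})

test_that("signed-rank test matches closed forms and enumeration", {
  expect_error(wilcoxonPaired(1:5, 1:5), "zero")
  ## n = 6, all differences positive: two-sided exact p = 2/64
  w <- wilcoxonPaired(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
  expect_equal(w$statistic, 21)
  expect_equal(w$pValue, 0.03125)
  ## n = 12 random sample vs exhaustive sign-flip enumeration
  set.seed(17)
  a <- rnorm(12); b <- rnorm(12)
  d <- a - b; d <- d[d != 0]; n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  flips <- expand.grid(rep(list(c(0, 1)), n))
  Ws <- as.matrix(flips) %*% r
  pEnum <- min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
  expect_equal(wilcoxonPaired(a, b)$pValue, pEnum, tolerance = 1e-12)
  ## cross-check against the standard implementation (no ties)
  wt <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxonPaired(a, b)$pValue, wt$p.value, tolerance = 1e-12)
})

test_that("enrichment matches direct hypergeometric summation", {
  ann <- data.frame(target = c(1:4, 5:8, 1L, 9L),
                    pathway = c(rep(1L, 4), rep(2L, 4), 3L, 3L),
                    type = "KEGG")
  bg <- 1:40
  res <- enrichment(predicted = 1:4, annotations = ann, background = bg)
  ## pathway 1 fully recovered: smallest p
  expect_equal(res$pathway[1], 1L)
  p1 <- res$p[res$pathway == 1]
  ## direct summation: P(X >= 4), K = 4, N = 40, n = 4
  direct <- sum(vapply(4:4, function(x)
    choose(4, x) * choose(36, 4 - x) / choose(40, 4), numeric(1)))
  expect_equal(p1, direct, tolerance = 1e-12)
  ## zero overlap: one-sided tail is 1
  p2 <- res$p[res$pathway == 2]
  expect_equal(p2, 1)
  ## BH ordering and bounds
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(enrichment(integer(), ann, bg), "empty")
  expect_error(enrichment(99L, ann, bg), "background")
})

test_that("metric aggregation uses the sample standard deviation", {
  agg <- aggregateMetrics(list(c(rocAuc = 80), c(rocAuc = 90)))
  expect_equal(agg$mean, 85)
  expect_equal(agg$sd, sd(c(80, 90)))
  expect_equal(agg$sd, 7.0710678, tolerance = 1e-6)
})
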