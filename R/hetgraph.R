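## The pathway-enhanced heterogeneous graph: targets + pathways, 19 typed
## edge sets plus target self-loops, and the structural perturbations used
## by ablations and robustness protocols.

.PPI_UNDIRECTED <- setdiff(.PPI_CATEGORIES, .PPI_DIRECTED)
.INV_PPI_LABELS <- paste0("inv_", .PPI_DIRECTED)
.ANN_LABELS     <- paste0("ann_", .ANNOTATION_TYPES)
.INV_ANN_LABELS <- paste0("inv_ann_", .ANNOTATION_TYPES)

#' The 19-relation edge-type registry
#'
#' Seven PPI categories, four inverse labels for the directional categories,
#' four annotation labels (one per origin type) and their four inverses.
#' The reserved `self_loop` label is kept outside the 19.
#'
#' @return character vector of the 19 relation labels.
#' @export
edgeTypeRegistry <- function() {
  c(.PPI_CATEGORIES, .INV_PPI_LABELS, .ANN_LABELS, .INV_ANN_LABELS)
}

## PPI-derived relation labels (the ones the inner propagation loop visits).
.ppiRelationLabels <- function(graph) {
  intersect(names(graph@edges),
            c(.PPI_CATEGORIES, .INV_PPI_LABELS, "ppi"))
}

.emptyEdges <- function() matrix(integer(), 0, 2)

#' Build the heterogeneous graph from a knowledge base
#'
#' PPI records with combined score below `minCombinedScore` are excluded
#' (high-confidence scaffold). Undirected categories (binary, complexes,
#' literature) are materialized with both orientations under one label;
#' directional categories produce forward and inverse (`inv_*`) edge sets;
#' annotations produce forward and inverse sets per origin type; every
#' target receives exactly one self-loop. Edges are unweighted. Herb nodes
#' never enter the graph.
#'
#' @param kb a KnowledgeBase.
#' @param minCombinedScore STRING-style combined-score threshold, default 700.
#' @return a [HeteroGraph-class] with `nNodes(g) == nTargets + nPathways`.
#' @export
buildGraph <- function(kb, minCombinedScore = 700L) {
  n <- entityCounts(kb)
  nT <- n[["target"]]; nP <- n[["pathway"]]
  pp <- kb@ppis[kb@ppis$combined_score >= minCombinedScore, , drop = FALSE]
  edges <- list()
  for (cat in .PPI_CATEGORIES) {
    e <- pp[pp$category == cat, c("src", "dst")]
    em <- unname(as.matrix(e))
    if (cat %in% .PPI_UNDIRECTED) {
      both <- rbind(em, em[, 2:1, drop = FALSE])
      edges[[cat]] <- unique(both)
    } else {
      edges[[cat]] <- unique(em)
      edges[[paste0("inv_", cat)]] <- unique(em[, 2:1, drop = FALSE])
    }
  }
  for (ty in .ANNOTATION_TYPES) {
    a <- kb@annotations[kb@annotations$type == ty, c("target", "pathway")]
    am <- unname(as.matrix(a))
    edges[[paste0("ann_", ty)]] <- unique(am)
    edges[[paste0("inv_ann_", ty)]] <- unique(am[, 2:1, drop = FALSE])
  }
  for (rel in names(edges)) {
    if (!nrow(edges[[rel]])) {
      warning("relation '", rel, "' is empty")
      edges[[rel]] <- .emptyEdges()
    }
    storage.mode(edges[[rel]]) <- "integer"
  }
  edges$self_loop <- cbind(seq_len(nT), seq_len(nT))
  new("HeteroGraph", nTargets = as.integer(nT), nPathways = as.integer(nP),
      edges = edges)
}

## Forward-edge units of a graph: one row per distinct interaction. For
## undirected PPI relations (stored symmetrically) a unit is the unordered
## pair; for directed and annotation relations it is the stored forward edge.
.forwardUnits <- function(graph) {
  out <- list()
  for (rel in names(graph@edges)) {
    if (rel == "self_loop" || startsWith(rel, "inv_")) next
    e <- graph@edges[[rel]]
    if (!nrow(e)) next
    if (rel %in% c(.PPI_UNDIRECTED, "ppi")) {
      u <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
      out[[rel]] <- data.frame(rel = rel, a = u[, 1], b = u[, 2])
    } else {
      out[[rel]] <- data.frame(rel = rel, a = e[, 1], b = e[, 2])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## Rebuild relation edge lists after dropping a subset of forward units.
.unitsToGraph <- function(graph, units) {
  edges <- graph@edges
  for (rel in names(edges)) {
    if (rel == "self_loop") next
    if (startsWith(rel, "inv_")) next
    u <- units[units$rel == rel, , drop = FALSE]
    em <- cbind(u$a, u$b)
    storage.mode(em) <- "integer"
    if (rel %in% c(.PPI_UNDIRECTED, "ppi")) {
      edges[[rel]] <- unique(rbind(em, em[, 2:1, drop = FALSE]))
    } else {
      edges[[rel]] <- em
      inv <- paste0("inv_", rel)
      if (inv %in% names(edges))
        edges[[inv]] <- em[, 2:1, drop = FALSE]
    }
  }
  new("HeteroGraph", nTargets = graph@nTargets, nPathways = graph@nPathways,
      edges = edges)
}

#' Knowledge erosion: random removal of graph edges
#'
#' Removes `round(fraction * E)` forward edges uniformly at random over the
#' union of all non-self-loop forward edges; an eroded forward edge takes
#' its inverse twin (or mirror orientation) with it. Self-loops are never
#' removed. Deterministic in `seed`.
#'
#' @param graph a HeteroGraph.
#' @param fraction fraction of forward edges to remove, in [0,1].
#' @param seed integer seed.
#' @return the eroded HeteroGraph.
#' @export
erodeGraph <- function(graph, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(graph)
  units <- .forwardUnits(graph)
  nDrop <- round(fraction * nrow(units))
  if (nDrop == 0) return(graph)
  drop <- .withSeed(seed, sample.int(nrow(units), nDrop))
  .unitsToGraph(graph, units[-drop, , drop = FALSE])
}

#' Collapse all PPI relation types into one homogeneous relation
#'
#' Merges the 11 PPI-derived relations (with de-duplication of repeated
#' pairs) into a single undirected `ppi` relation; pathway relations and
#' self-loops are untouched. Idempotent.
#'
#' @param graph a HeteroGraph.
#' @return the collapsed HeteroGraph.
#' @export
collapsePpiTypes <- function(graph) {
  rels <- .ppiRelationLabels(graph)
  pairs <- do.call(rbind, lapply(rels, function(r) graph@edges[[r]]))
  edges <- graph@edges[setdiff(names(graph@edges),
                               c(.PPI_CATEGORIES, .INV_PPI_LABELS, "ppi"))]
  if (is.null(pairs) || !nrow(pairs)) {
    merged <- .emptyEdges()
  } else {
    u <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2])))
    merged <- unique(rbind(u, u[, 2:1, drop = FALSE]))
    storage.mode(merged) <- "integer"
  }
  edges <- c(list(ppi = merged), edges)
  new("HeteroGraph", nTargets = graph@nTargets, nPathways = graph@nPathways,
      edges = edges)
}

#' Remove pathway nodes and all annotation relations
#'
#' Drops the 8 annotation edge sets and the pathway layer entirely;
#' target-side relations are untouched.
#'
#' @param graph a HeteroGraph.
#' @return HeteroGraph with `nPathways == 0`.
#' @export
stripPathways <- function(graph) {
  keep <- setdiff(names(graph@edges), c(.ANN_LABELS, .INV_ANN_LABELS))
  new("HeteroGraph", nTargets = graph@nTargets, nPathways = 0L,
      edges = graph@edges[keep])
}

#' PPI degree of every target
#'
#' Number of distinct PPI partners over all PPI relations, ignoring pathway
#' edges and self-loops. This is the degree used for stratified evaluation
#' and for the degree baseline.
#'
#' @param graph a HeteroGraph.
#' @return integer vector of length `nTargets`.
#' @export
ppiDegree <- function(graph) {
  rels <- .ppiRelationLabels(graph)
  pairs <- do.call(rbind, lapply(rels, function(r) graph@edges[[r]]))
  deg <- integer(graph@nTargets)
  if (!is.null(pairs) && nrow(pairs)) {
    both <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
    tab <- table(factor(both[, 1], levels = seq_len(graph@nTargets)))
    deg <- as.integer(tab)
  }
  deg
}

#' Write a graph as per-relation edge TSVs
#'
#' @param graph a HeteroGraph.
#' @param dir output directory.
#' @export
writeGraph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(data.frame(n_targets = graph@nTargets,
                       n_pathways = graph@nPathways),
            file.path(dir, "nodes.tsv"))
  for (rel in names(graph@edges)) {
    e <- graph@edges[[rel]]
    .writeTsv(data.frame(from = e[, 1], to = e[, 2]),
              file.path(dir, sprintf("edges.%s.tsv", rel)))
  }
  invisible(dir)
}
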