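## Generics, accessors and show methods.

#' Entity counts of a knowledge base
#'
#' @param x a KnowledgeBase.
#' @return named integer vector with one count per entity class.
#' @export
setGeneric("entityCounts", function(x) standardGeneric("entityCounts"))

#' @rdname entityCounts
#' @export
setMethod("entityCounts", "KnowledgeBase", function(x) {
  vapply(x@registries, length, integer(1))
})

#' Registry accessor
#'
#' @param x a KnowledgeBase.
#' @param class one of the six entity class names.
#' @return character vector of external identifiers.
#' @export
setGeneric("registry", function(x, class) standardGeneric("registry"))

#' @rdname registry
#' @export
setMethod("registry", "KnowledgeBase", function(x, class) {
  class <- match.arg(class, .ENTITY_CLASSES)
  x@registries[[class]]
})

#' Herb-target interaction records (supervision labels)
#' @param x a KnowledgeBase.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname interactions
#' @export
setMethod("interactions", "KnowledgeBase", function(x) x@interactions)

#' Typed protein-protein interaction records
#' @param x a KnowledgeBase.
#' @export
setGeneric("ppis", function(x) standardGeneric("ppis"))

#' @rdname ppis
#' @export
setMethod("ppis", "KnowledgeBase", function(x) x@ppis)

#' Target-pathway annotation records
#' @param x a KnowledgeBase or HeteroGraph-bearing object.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname annotations
#' @export
setMethod("annotations", "KnowledgeBase", function(x) x@annotations)

#' Association matrix accessor
#'
#' @param x a KnowledgeBase.
#' @param rel one of "HT", "TM", "MD", "DT".
#' @return a sparse dgCMatrix.
#' @export
setGeneric("assocMatrix", function(x, rel) standardGeneric("assocMatrix"))

#' @rdname assocMatrix
#' @export
setMethod("assocMatrix", "KnowledgeBase", function(x, rel) {
  rel <- match.arg(rel, c("HT", "TM", "MD", "DT"))
  slot(x, paste0("M_", rel))
})

#' Edge index matrix of one relation
#'
#' @param x a HeteroGraph.
#' @param rel relation label.
#' @export
setGeneric("edges", function(x, rel) standardGeneric("edges"))

#' @rdname edges
#' @export
setMethod("edges", "HeteroGraph", function(x, rel) {
  if (!rel %in% names(x@edges)) stop("unknown relation: ", rel)
  x@edges[[rel]]
})

#' Per-relation edge counts
#' @param x a HeteroGraph.
#' @export
setGeneric("edgeCounts", function(x) standardGeneric("edgeCounts"))

#' @rdname edgeCounts
#' @export
setMethod("edgeCounts", "HeteroGraph", function(x) {
  vapply(x@edges, nrow, integer(1))
})

#' Total node count (targets + pathways)
#' @param x a HeteroGraph.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "HeteroGraph", function(x) x@nTargets + x@nPathways)

#' Positive (herb, target, confidence) records of a dataset
#' @param x a TripletDataset.
#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @rdname positives
#' @export
setMethod("positives", "TripletDataset", function(x) x@positives)

#' Herbs retained by a dataset recipe
#' @param x a TripletDataset.
#' @export
setGeneric("eligibleHerbs", function(x) standardGeneric("eligibleHerbs"))

#' @rdname eligibleHerbs
#' @export
setMethod("eligibleHerbs", "TripletDataset", function(x) x@eligibleHerbs)

setMethod("show", "KnowledgeBase", function(object) {
  n <- entityCounts(object)
  cat("KnowledgeBase\n")
  cat("  entities:", paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  cat(sprintf("  associations: HT=%d TM=%d MD=%d DT=%d\n",
              length(object@M_HT@x), length(object@M_TM@x),
              length(object@M_MD@x), length(object@M_DT@x)))
  cat(sprintf("  interactions: %d   ppis: %d   annotations: %d\n",
              nrow(object@interactions), nrow(object@ppis),
              nrow(object@annotations)))
})

setMethod("show", "HeteroGraph", function(object) {
  ec <- edgeCounts(object)
  cat(sprintf("HeteroGraph: %d targets + %d pathways = %d nodes\n",
              object@nTargets, object@nPathways, nNodes(object)))
  cat(sprintf("  %d relations (excl. self_loop), %d edges total\n",
              sum(names(ec) != "self_loop"),
              sum(ec[names(ec) != "self_loop"])))
})

setMethod("show", "TripletDataset", function(object) {
  cat(sprintf("TripletDataset '%s': %d positives over %d herbs\n",
              object@recipe$name, nrow(object@positives),
              length(object@eligibleHerbs)))
})
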