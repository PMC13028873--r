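## Central S4 data containers.

#' @importFrom methods new validObject is as setClass setGeneric setMethod
#' @importFrom Matrix sparseMatrix Diagonal t rowSums colSums
NULL

## Entity classes of the knowledge base, in canonical order.
.ENTITY_CLASSES <- c("herb", "tcm_symptom", "mm_symptom", "disease",
                     "target", "pathway")

## The seven PPI relation categories; four are biologically directional.
.PPI_CATEGORIES <- c("binary", "complexes", "kinase", "literature",
                     "metabolic", "regulatory", "signaling")
.PPI_DIRECTED   <- c("kinase", "metabolic", "regulatory", "signaling")

## Pathway annotation origins.
.ANNOTATION_TYPES <- c("KEGG", "GO_BP", "GO_MF", "GO_CC")

.asSparse <- function(m) {
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' KnowledgeBase: the multi-scale pharmacological knowledge base
#'
#' Holds entity registries for the six entity classes (herb, TCM symptom,
#' modern-medicine symptom, disease, target, pathway), the four sparse
#' association matrices of the phenotype-to-target cascade, confidence-scored
#' herb-target interaction records (supervision labels, never graph edges),
#' typed protein-protein interaction records and target-pathway annotations.
#'
#' Internally all cross-references are dense 1-based integer indices into the
#' registries; external identifiers are opaque strings.
#'
#' @slot registries named list of character vectors, one per entity class.
#' @slot M_HT herb x TCM-symptom binary association matrix.
#' @slot M_TM TCM-symptom x MM-symptom association matrix, weights in (0,1].
#' @slot M_MD MM-symptom x disease association matrix.
#' @slot M_DT disease x target association matrix.
#' @slot interactions data.frame(herb, target, confidence, p_value).
#' @slot ppis data.frame(src, dst, category, combined_score).
#' @slot annotations data.frame(target, pathway, type).
#' @export
setClass("KnowledgeBase", slots = c(
  registries   = "list",
  M_HT         = "dgCMatrix",
  M_TM         = "dgCMatrix",
  M_MD         = "dgCMatrix",
  M_DT         = "dgCMatrix",
  interactions = "data.frame",
  ppis         = "data.frame",
  annotations  = "data.frame"
))

setValidity("KnowledgeBase", function(object) {
  msg <- character()
  reg <- object@registries
  if (!identical(sort(names(reg)), sort(.ENTITY_CLASSES)))
    msg <- c(msg, "registries must cover exactly the six entity classes")
  for (cl in intersect(names(reg), .ENTITY_CLASSES)) {
    if (anyDuplicated(reg[[cl]]))
      msg <- c(msg, sprintf("duplicate identifiers in registry '%s'", cl))
  }
  n <- vapply(reg, length, integer(1))
  dims <- list(
    M_HT = c("herb", "tcm_symptom"),
    M_TM = c("tcm_symptom", "mm_symptom"),
    M_MD = c("mm_symptom", "disease"),
    M_DT = c("disease", "target"))
  for (nm in names(dims)) {
    m <- slot(object, nm)
    want <- unname(n[dims[[nm]]])
    if (!identical(dim(m), as.integer(want)))
      msg <- c(msg, sprintf("%s has shape %s, expected %s", nm,
                            paste(dim(m), collapse = "x"),
                            paste(want, collapse = "x")))
    if (length(m@x) && (any(m@x <= 0) || any(m@x > 1)))
      msg <- c(msg, sprintf("%s weights must lie in (0,1]", nm))
  }
  it <- object@interactions
  if (nrow(it)) {
    if (anyDuplicated(it[c("herb", "target")]))
      msg <- c(msg, "duplicate (herb, target) interaction records")
    if (any(it$herb < 1L | it$herb > n["herb"]) ||
        any(it$target < 1L | it$target > n["target"]))
      msg <- c(msg, "interaction index out of range")
    if (any(!is.finite(it$confidence)) ||
        any(it$confidence < 0 | it$confidence > 1))
      msg <- c(msg, "interaction confidence must lie in [0,1]")
  }
  pp <- object@ppis
  if (nrow(pp)) {
    if (!all(pp$category %in% .PPI_CATEGORIES))
      msg <- c(msg, "unknown PPI category")
    if (any(pp$src == pp$dst))
      msg <- c(msg, "PPI self-pairs are not allowed")
    if (any(pp$src < 1L | pp$src > n["target"]) ||
        any(pp$dst < 1L | pp$dst > n["target"]))
      msg <- c(msg, "PPI index out of range")
    if (any(pp$combined_score < 0L | pp$combined_score > 1000L))
      msg <- c(msg, "combined_score must lie in 0..1000")
  }
  an <- object@annotations
  if (nrow(an)) {
    if (!all(an$type %in% .ANNOTATION_TYPES))
      msg <- c(msg, "unknown annotation type")
    if (anyDuplicated(an[c("target", "pathway", "type")]))
      msg <- c(msg, "duplicate (target, pathway, type) annotation")
    if (any(an$target < 1L | an$target > n["target"]) ||
        any(an$pathway < 1L | an$pathway > n["pathway"]))
      msg <- c(msg, "annotation index out of range")
    ## every pathway node carries exactly one origin type
    byp <- tapply(an$type, an$pathway, function(x) length(unique(x)))
    if (any(byp > 1L))
      msg <- c(msg, "a pathway node must carry exactly one annotation type")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KnowledgeBase
#'
#' @param registries named list of character identifier vectors for the six
#'   entity classes.
#' @param M_HT,M_TM,M_MD,M_DT association matrices (anything coercible to a
#'   sparse numeric matrix); `M_HT` is binary.
#' @param interactions data.frame with columns herb, target (1-based integer
#'   indices), confidence and optionally p_value.
#' @param ppis data.frame with columns src, dst, category, combined_score.
#' @param annotations data.frame with columns target, pathway, type.
#' @return a validated [KnowledgeBase-class] object.
#' @export
knowledgeBase <- function(registries, M_HT, M_TM, M_MD, M_DT,
                          interactions = emptyInteractions(),
                          ppis = emptyPpis(),
                          annotations = emptyAnnotations()) {
  if (!"p_value" %in% names(interactions)) interactions$p_value <- NA_real_
  interactions$herb <- as.integer(interactions$herb)
  interactions$target <- as.integer(interactions$target)
  ppis$src <- as.integer(ppis$src); ppis$dst <- as.integer(ppis$dst)
  ppis$combined_score <- as.integer(ppis$combined_score)
  annotations$target <- as.integer(annotations$target)
  annotations$pathway <- as.integer(annotations$pathway)
  new("KnowledgeBase", registries = registries[.ENTITY_CLASSES],
      M_HT = .asSparse(M_HT), M_TM = .asSparse(M_TM),
      M_MD = .asSparse(M_MD), M_DT = .asSparse(M_DT),
      interactions = interactions, ppis = ppis, annotations = annotations)
}

#' @rdname knowledgeBase
#' @export
emptyInteractions <- function() {
  data.frame(herb = integer(), target = integer(),
             confidence = numeric(), p_value = numeric())
}

#' @rdname knowledgeBase
#' @export
emptyPpis <- function() {
  data.frame(src = integer(), dst = integer(),
             category = character(), combined_score = integer())
}

#' @rdname knowledgeBase
#' @export
emptyAnnotations <- function() {
  data.frame(target = integer(), pathway = integer(), type = character())
}

#' HeteroGraph: the pathway-enhanced heterogeneous graph
#'
#' Targets and pathways as nodes; 19 typed edge sets (7 PPI categories, 4
#' inverse edge sets for the directional categories, 4 annotation edge sets,
#' 4 inverse annotation edge sets) plus a reserved `self_loop` relation kept
#' outside the 19. Undirected PPI categories are materialized symmetrically
#' (both orientations) under a single label. Herb nodes never exist in the
#' graph; herb-target supervision never enters any relation.
#'
#' @slot nTargets,nPathways node counts of the two layers.
#' @slot edges named list of 2-column integer matrices (from, to), one per
#'   relation; annotation relations point target -> pathway, their inverses
#'   pathway -> target.
#' @export
setClass("HeteroGraph", slots = c(
  nTargets  = "integer",
  nPathways = "integer",
  edges     = "list"
))

setValidity("HeteroGraph", function(object) {
  msg <- character()
  for (rel in names(object@edges)) {
    e <- object@edges[[rel]]
    if (!is.matrix(e) || ncol(e) != 2L)
      msg <- c(msg, sprintf("relation '%s' must be a 2-column matrix", rel))
  }
  if (!"self_loop" %in% names(object@edges))
    msg <- c(msg, "missing self_loop relation")
  if (length(msg)) msg else TRUE
})

#' TripletDataset: supervision positives under a stratified recipe
#'
#' @slot positives data.frame(herb, target, confidence) filtered by the
#'   recipe's confidence band and significance threshold.
#' @slot eligibleHerbs integer herb indices retained by the recipe.
#' @slot recipe the [datasetRecipe()] that produced the dataset.
#' @slot nHerbs,nTargets context sizes of the source knowledge base.
#' @export
setClass("TripletDataset", slots = c(
  positives     = "data.frame",
  eligibleHerbs = "integer",
  recipe        = "list",
  nHerbs        = "integer",
  nTargets      = "integer"
))

setValidity("TripletDataset", function(object) {
  p <- object@positives
  msg <- character()
  if (!all(c("herb", "target", "confidence") %in% names(p)))
    msg <- c(msg, "positives needs herb, target, confidence columns")
  if (nrow(p) && !all(p$herb %in% object@eligibleHerbs))
    msg <- c(msg, "positives reference non-eligible herbs")
  if (length(msg)) msg else TRUE
})
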