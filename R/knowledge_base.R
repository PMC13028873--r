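## Delimited-text readers/writers and QC filters for the knowledge base.
##
## On-disk layout (tab-separated, header row, opaque string identifiers):
##   entities.<class>.tsv   id [, name]
##   assoc.herb_tcm.tsv     row_id  col_id [, confidence]     (M_HT)
##   assoc.tcm_mm.tsv       row_id  col_id [, confidence]     (M_TM)
##   assoc.mm_disease.tsv   ...                               (M_MD)
##   assoc.disease_target.tsv                                 (M_DT)
##   ppi.tsv                src  dst  category  combined_score
##   annotations.tsv        target_id  pathway_id  type
##   interactions.tsv       herb_id  target_id  confidence  p_value

.ASSOC_FILES <- c(HT = "assoc.herb_tcm.tsv",  TM = "assoc.tcm_mm.tsv",
                  MD = "assoc.mm_disease.tsv", DT = "assoc.disease_target.tsv")
.ASSOC_CLASSES <- list(HT = c("herb", "tcm_symptom"),
                       TM = c("tcm_symptom", "mm_symptom"),
                       MD = c("mm_symptom", "disease"),
                       DT = c("disease", "target"))

.readTsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

## Map external ids to dense indices; dangling ids are an error, never dropped.
.resolveIds <- function(ids, registry, file, what) {
  idx <- match(ids, registry)
  if (anyNA(idx)) {
    bad <- unique(ids[is.na(idx)])
    stop(sprintf("unknown %s identifier(s) in %s: %s", what, file,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  idx
}

.assocFromPairs <- function(ri, ci, w, nr, nc) {
  if (anyDuplicated(cbind(ri, ci)))
    stop("duplicate (row, col) association pairs")
  Matrix::sparseMatrix(i = ri, j = ci, x = w, dims = c(nr, nc))
}

#' Load a knowledge base from a directory of TSV tables
#'
#' Unknown identifiers in any edge table are an error naming the identifier
#' and file, never silently dropped.
#'
#' @param dir directory holding the TSV tables (see the package vignette for
#'   the dialect).
#' @return a [KnowledgeBase-class].
#' @export
loadKnowledgeBase <- function(dir) {
  reg <- list()
  for (cl in .ENTITY_CLASSES) {
    f <- file.path(dir, sprintf("entities.%s.tsv", cl))
    tab <- .readTsv(f)
    if (!"id" %in% names(tab)) stop("no 'id' column in ", f)
    reg[[cl]] <- as.character(tab$id)
  }
  n <- vapply(reg, length, integer(1))
  mats <- list()
  for (rel in names(.ASSOC_FILES)) {
    f <- file.path(dir, .ASSOC_FILES[[rel]])
    tab <- .readTsv(f)
    cls <- .ASSOC_CLASSES[[rel]]
    ri <- .resolveIds(as.character(tab$row_id), reg[[cls[1]]], f, cls[1])
    ci <- .resolveIds(as.character(tab$col_id), reg[[cls[2]]], f, cls[2])
    w <- if ("confidence" %in% names(tab)) as.numeric(tab$confidence)
         else rep(1, nrow(tab))
    if (length(w) && (any(!is.finite(w)) || any(w <= 0 | w > 1)))
      stop("malformed confidence (outside (0,1]) in ", f)
    mats[[rel]] <- .assocFromPairs(ri, ci, w, n[cls[1]], n[cls[2]])
  }
  f <- file.path(dir, "ppi.tsv")
  pp <- .readTsv(f)
  ppis <- data.frame(
    src = .resolveIds(as.character(pp$src), reg$target, f, "target"),
    dst = .resolveIds(as.character(pp$dst), reg$target, f, "target"),
    category = as.character(pp$category),
    combined_score = as.integer(pp$combined_score))
  f <- file.path(dir, "annotations.tsv")
  an <- .readTsv(f)
  annotations <- data.frame(
    target = .resolveIds(as.character(an$target_id), reg$target, f, "target"),
    pathway = .resolveIds(as.character(an$pathway_id), reg$pathway, f,
                          "pathway"),
    type = as.character(an$type))
  f <- file.path(dir, "interactions.tsv")
  it <- .readTsv(f)
  conf <- as.numeric(it$confidence)
  if (length(conf) && (any(!is.finite(conf)) || any(conf < 0 | conf > 1)))
    stop("malformed confidence (outside [0,1]) in ", f)
  interactions <- data.frame(
    herb = .resolveIds(as.character(it$herb_id), reg$herb, f, "herb"),
    target = .resolveIds(as.character(it$target_id), reg$target, f, "target"),
    confidence = conf,
    p_value = if ("p_value" %in% names(it)) as.numeric(it$p_value)
              else NA_real_)
  knowledgeBase(reg, mats$HT, mats$TM, mats$MD, mats$DT,
                interactions, ppis, annotations)
}

#' Write a knowledge base to a directory of TSV tables
#'
#' Inverse of [loadKnowledgeBase()]: `loadKnowledgeBase(writeKnowledgeBase(kb,
#' dir))` reproduces `kb` exactly.
#'
#' @param kb a KnowledgeBase.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in .ENTITY_CLASSES)
    .writeTsv(data.frame(id = kb@registries[[cl]]),
              file.path(dir, sprintf("entities.%s.tsv", cl)))
  for (rel in names(.ASSOC_FILES)) {
    m <- slot(kb, paste0("M_", rel))
    cls <- .ASSOC_CLASSES[[rel]]
    tm <- as(m, "TsparseMatrix")
    o <- order(tm@i, tm@j)
    .writeTsv(data.frame(row_id = kb@registries[[cls[1]]][tm@i[o] + 1L],
                         col_id = kb@registries[[cls[2]]][tm@j[o] + 1L],
                         confidence = tm@x[o]),
              file.path(dir, .ASSOC_FILES[[rel]]))
  }
  .writeTsv(data.frame(src = kb@registries$target[kb@ppis$src],
                       dst = kb@registries$target[kb@ppis$dst],
                       category = kb@ppis$category,
                       combined_score = kb@ppis$combined_score),
            file.path(dir, "ppi.tsv"))
  .writeTsv(data.frame(target_id = kb@registries$target[kb@annotations$target],
                       pathway_id = kb@registries$pathway[kb@annotations$pathway],
                       type = kb@annotations$type),
            file.path(dir, "annotations.tsv"))
  .writeTsv(data.frame(herb_id = kb@registries$herb[kb@interactions$herb],
                       target_id = kb@registries$target[kb@interactions$target],
                       confidence = kb@interactions$confidence,
                       p_value = kb@interactions$p_value),
            file.path(dir, "interactions.tsv"))
  invisible(dir)
}

#' Quality-control filter for symptom-side associations
#'
#' Removes symptom-side association records with confidence below
#' `minConfidence`, then removes generic TCM symptoms (those linked to more
#' than `genericSymptomFraction` of all herbs) from the TCM-symptom registry,
#' `M_HT` and `M_TM`, re-indexing densely. Herb-target interaction records
#' are untouched: their confidence thresholds belong to the dataset recipes.
#' The filter is idempotent.
#'
#' @param kb a KnowledgeBase.
#' @param minConfidence confidence threshold in (0,1]; association entries
#'   with weight below it are dropped (default 0.8).
#' @param genericSymptomFraction a TCM symptom touching more than this
#'   fraction of all herbs is considered generic and removed (default 0.25).
#' @return the filtered, re-indexed KnowledgeBase.
#' @export
qcFilter <- function(kb, minConfidence = 0.8, genericSymptomFraction = 0.25) {
  stopifnot(minConfidence > 0, minConfidence <= 1,
            genericSymptomFraction > 0, genericSymptomFraction <= 1)
  drop_low <- function(m) {
    m@x[m@x < minConfidence] <- 0
    Matrix::drop0(m)
  }
  M_HT <- drop_low(kb@M_HT)
  M_TM <- drop_low(kb@M_TM)
  M_MD <- drop_low(kb@M_MD)
  M_DT <- drop_low(kb@M_DT)
  nHerbs <- length(kb@registries$herb)
  herbsPerSymptom <- Matrix::colSums(M_HT != 0)
  keep <- which(herbsPerSymptom <= genericSymptomFraction * nHerbs)
  if (!length(keep))
    stop("QC filter removed every TCM symptom (empty phenotype space)")
  reg <- kb@registries
  reg$tcm_symptom <- reg$tcm_symptom[keep]
  knowledgeBase(reg, M_HT[, keep, drop = FALSE],
                M_TM[keep, , drop = FALSE], M_MD, M_DT,
                kb@interactions, kb@ppis, kb@annotations)
}

#' Symptom profile of one herb
#'
#' The binary phenotype vector read off the herb row of `M_HT`; defined for
#' herbs with zero recorded interactions (the cold-start case). An all-zero
#' profile is allowed but flagged with a warning.
#'
#' @param kb a KnowledgeBase.
#' @param herb 1-based herb index.
#' @return 0/1 numeric vector of length `N_s` (TCM symptoms).
#' @export
symptomVector <- function(kb, herb) {
  n <- entityCounts(kb)
  if (herb < 1L || herb > n["herb"]) stop("herb index out of bounds")
  v <- as.numeric(kb@M_HT[herb, ] != 0)
  if (!any(v > 0))
    warning("herb ", herb, " has an empty symptom profile")
  v
}

#' Symptom profiles for several herbs at once
#'
#' @param kb a KnowledgeBase.
#' @param herbs integer herb indices.
#' @return binary matrix, one row per herb, `N_s` columns.
#' @export
symptomMatrix <- function(kb, herbs) {
  m <- kb@M_HT[herbs, , drop = FALSE]
  m@x[] <- 1
  as.matrix(m)
}
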