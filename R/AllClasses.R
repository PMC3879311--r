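#' ExpressionMatrix: entities by tissue/cell-type expression scores
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay named
#' \code{"score"}: a grid of finite, nonnegative expression scores for
#' entities (lncRNAs or genes, rows) across tissue or cell-type conditions
#' (columns). Row names are entity identifiers; column names are condition
#' labels, stored in normalized (trimmed, case-folded) form so two matrices
#' produced independently can be aligned by name. BED-like positional
#' annotation (chrom, start, end) read from UCSC-style tables is carried as
#' opaque columns in \code{rowData}.
#'
#' Validity requires: at least 1 entity and at least 2 conditions; unique,
#' non-empty entity IDs and condition labels; every score finite and >= 0.
#'
#' @seealso [readExpressionTable()], [filterDegenerate()],
#'   [partitionBySpecificity()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msgs <- character(0)
  if (!"score" %in% SummarizedExperiment::assayNames(object))
    return("assay 'score' is missing")
  v <- SummarizedExperiment::assay(object, "score")
  if (nrow(v) < 1L)
    msgs <- c(msgs, "at least 1 entity (row) is required")
  if (ncol(v) < 2L)
    msgs <- c(msgs, "at least 2 conditions (columns) are required")
  if (is.null(rownames(v)) || anyNA(rownames(v)) || any(rownames(v) == ""))
    msgs <- c(msgs, "entity IDs (rownames) must be present and non-empty")
  else if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, sprintf("duplicate entity ID: '%s'",
                            rownames(v)[duplicated(rownames(v))][1L]))
  if (is.null(colnames(v)) || anyNA(colnames(v)) || any(colnames(v) == ""))
    msgs <- c(msgs, "condition labels (colnames) must be present and non-empty")
  else if (anyDuplicated(colnames(v)))
    msgs <- c(msgs, sprintf("duplicate condition label: '%s'",
                            colnames(v)[duplicated(colnames(v))][1L]))
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    msgs <- c(msgs, "all expression values must be finite numbers")
  else if (any(v < 0))
    msgs <- c(msgs, "expression values must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (entities x conditions) with rownames
#'   (entity IDs) and colnames (condition labels). Labels are normalized
#'   with [normalizeConditionLabels()].
#' @param rowData optional data.frame of per-entity annotation (e.g. the
#'   chrom/start/end columns of a BED-like table), carried opaquely.
#' @param saturationValue optional upper score bound recorded in
#'   \code{metadata()} (1000 for UCSC score tracks); informational only.
#' @return an \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(c(5, 0, 3, 9, 1, 2), nrow = 2,
#'             dimnames = list(c("lnc1", "lnc2"), c("lung", "brain", "liver")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, rowData = NULL, saturationValue = NULL) {
  values <- as.matrix(values)
  if (!is.null(colnames(values)))
    colnames(values) <- normalizeConditionLabels(colnames(values))
  args <- list(assays = list(score = values))
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  obj <- methods::new("ExpressionMatrix", se)
  if (!is.null(saturationValue))
    S4Vectors::metadata(obj)$saturation_value <- saturationValue
  obj
}

#' GeneDiseaseMap: gene-disease association table with a disease index
#'
#' Stores unique (gene, disease) association pairs, e.g. a DisGeNET extract,
#' plus the derived index disease -> gene set used by disease enrichment.
#' Validity requires unique pairs and a nonempty gene set for every disease.
#'
#' @seealso [readGeneDiseaseTable()], [enrichDiseases()]
#' @export
setClass("GeneDiseaseMap",
         representation(pairs = "data.frame", index = "list"))

setValidity("GeneDiseaseMap", function(object) {
  p <- object@pairs
  if (!identical(colnames(p), c("gene_id", "disease_id")))
    return("pairs must have columns gene_id, disease_id")
  if (nrow(p) < 1L)
    return("at least one gene-disease pair is required")
  if (anyDuplicated(.pairKey(p$gene_id, p$disease_id)))
    return("duplicate (gene, disease) pairs")
  if (!length(object@index) || any(!lengths(object@index)))
    return("every disease must index a nonempty gene set")
  TRUE
})

#' Construct a GeneDiseaseMap from a pair table
#'
#' Duplicate pairs are deduplicated (with a logged count): curated
#' gene-disease databases merge several sources, so repeats are expected.
#'
#' @param pairs data.frame whose first two columns are gene ID and disease ID.
#' @return a \linkS4class{GeneDiseaseMap}.
#' @examples
#' GeneDiseaseMap(data.frame(gene = c("g1", "g2"), disease = c("D1", "D1")))
#' @export
GeneDiseaseMap <- function(pairs) {
  pairs <- data.frame(gene_id = as.character(pairs[[1L]]),
                      disease_id = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  dup <- duplicated(.pairKey(pairs$gene_id, pairs$disease_id))
  if (any(dup)) {
    .logInfo("GeneDiseaseMap: deduplicated %d repeated pair(s)", sum(dup))
    pairs <- pairs[!dup, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  idx <- split(pairs$gene_id, pairs$disease_id)
  methods::new("GeneDiseaseMap", pairs = pairs, index = idx)
}

#' AssociationSet: a set of (lncRNA, disease) pairs
#'
#' Holds unique lncRNA-disease association pairs, used both for known
#' (experimentally verified) associations consumed by the evaluation harness
#' and for planted ground truth emitted by the synthetic generator.
#'
#' @seealso [readAssociationSet()], [loocv()]
#' @export
setClass("AssociationSet", representation(pairs = "data.frame"))

setValidity("AssociationSet", function(object) {
  p <- object@pairs
  if (!identical(colnames(p), c("lncrna_id", "disease_id")))
    return("pairs must have columns lncrna_id, disease_id")
  if (anyDuplicated(.pairKey(p$lncrna_id, p$disease_id)))
    return("duplicate (lncRNA, disease) pairs")
  TRUE
})

#' Construct an AssociationSet from a pair table
#'
#' @param pairs data.frame whose first two columns are lncRNA ID and
#'   disease ID; duplicates are deduplicated with a logged count.
#' @return an \linkS4class{AssociationSet}.
#' @examples
#' AssociationSet(data.frame(lnc = "L1", disease = c("D1", "D2")))
#' @export
AssociationSet <- function(pairs) {
  pairs <- data.frame(lncrna_id = as.character(pairs[[1L]]),
                      disease_id = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  dup <- duplicated(.pairKey(pairs$lncrna_id, pairs$disease_id))
  if (any(dup)) {
    .logInfo("AssociationSet: deduplicated %d repeated pair(s)", sum(dup))
    pairs <- pairs[!dup, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  methods::new("AssociationSet", pairs = pairs)
}

#' RocCurve: ROC points and area under the curve
#'
#' The result of a rank-threshold ROC sweep: (FPR, TPR) points from (0,0) to
#' (1,1), the rank threshold that produced each point, and the trapezoidal
#' area under the curve. AUC = 1 is perfect recovery of the known
#' associations, 0.5 is random performance.
#'
#' @seealso [rocAuc()], [loocv()]
#' @export
setClass("RocCurve", representation(points = "data.frame", auc = "numeric"))

setValidity("RocCurve", function(object) {
  p <- object@points
  if (!all(c("threshold", "fpr", "tpr") %in% colnames(p)))
    return("points must have columns threshold, fpr, tpr")
  if (nrow(p) < 2L)
    return("a curve needs at least the (0,0) and (1,1) points")
  if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
    return("fpr and tpr must be non-decreasing")
  if (p$fpr[1L] != 0 || p$tpr[1L] != 0)
    return("curve must start at (0,0)")
  if (p$fpr[nrow(p)] != 1 || p$tpr[nrow(p)] != 1)
    return("curve must end at (1,1)")
  if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
    return("auc must be a single value in [0,1]")
  TRUE
})
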