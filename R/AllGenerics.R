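#' @name lncDA-accessors
#' @title Accessors for lncDA data classes
#'
#' @description Slot access goes through accessors: \code{entityIds()} and
#' \code{conditionLabels()} return the row/column identifiers of an
#' \linkS4class{ExpressionMatrix} and \code{expressionValues()} its score
#' grid; \code{associationPairs()} returns the pair table of a
#' \linkS4class{GeneDiseaseMap} or \linkS4class{AssociationSet};
#' \code{diseaseGenes()} the disease -> gene set index; \code{rocPoints()}
#' and \code{aucValue()} the sweep points and area of a
#' \linkS4class{RocCurve}.
#'
#' @param x an lncDA object.
#' @return \code{entityIds}, \code{conditionLabels}: character vectors.
#'   \code{expressionValues}: numeric matrix. \code{associationPairs},
#'   \code{rocPoints}: data.frames. \code{diseaseGenes}: named list of
#'   character vectors. \code{aucValue}: single numeric.
#' @examples
#' m <- ExpressionMatrix(matrix(1:6, 2, 3,
#'        dimnames = list(c("a", "b"), c("x", "y", "z"))))
#' entityIds(m)
#' conditionLabels(m)
NULL

#' @rdname lncDA-accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname lncDA-accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname lncDA-accessors
#' @export
setGeneric("expressionValues", function(x) standardGeneric("expressionValues"))

#' @rdname lncDA-accessors
#' @export
setGeneric("associationPairs",
           function(x) standardGeneric("associationPairs"))

#' @rdname lncDA-accessors
#' @export
setGeneric("diseaseGenes", function(x) standardGeneric("diseaseGenes"))

#' @rdname lncDA-accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname lncDA-accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname lncDA-accessors
setMethod("entityIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname lncDA-accessors
setMethod("conditionLabels", "ExpressionMatrix", function(x) colnames(x))

#' @rdname lncDA-accessors
setMethod("expressionValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "score"))

#' @rdname lncDA-accessors
setMethod("associationPairs", "GeneDiseaseMap", function(x) x@pairs)

#' @rdname lncDA-accessors
setMethod("associationPairs", "AssociationSet", function(x) x@pairs)

#' @rdname lncDA-accessors
setMethod("diseaseGenes", "GeneDiseaseMap", function(x) x@index)

#' @rdname lncDA-accessors
setMethod("rocPoints", "RocCurve", function(x) x@points)

#' @rdname lncDA-accessors
setMethod("aucValue", "RocCurve", function(x) x@auc)

setMethod("show", "GeneDiseaseMap", function(object) {
  p <- object@pairs
  cat(sprintf("GeneDiseaseMap: %d associations between %d genes and %d diseases\n",
              nrow(p), length(unique(p$gene_id)),
              length(unique(p$disease_id))))
})

setMethod("show", "AssociationSet", function(object) {
  p <- object@pairs
  cat(sprintf("AssociationSet: %d lncRNA-disease pairs (%d lncRNAs, %d diseases)\n",
              nrow(p), length(unique(p$lncrna_id)),
              length(unique(p$disease_id))))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d threshold points, AUC = %.4f\n",
              nrow(object@points), object@auc))
})
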