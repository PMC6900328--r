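#' @rdname ExpressionCohort-accessors
#' @export
setGeneric("controlGroup", function(x) standardGeneric("controlGroup"))

#' @rdname ExpressionCohort-accessors
#' @export
setGeneric("cancerGroups", function(x) standardGeneric("cancerGroups"))

#' @rdname ExpressionCohort-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionCohort-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionCohort-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SelectionList-accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname RelativeExpression-accessors
#' @export
setGeneric("relMeans", function(x) standardGeneric("relMeans"))

#' @rdname RelativeExpression-accessors
#' @export
setGeneric("relRanks", function(x) standardGeneric("relRanks"))
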