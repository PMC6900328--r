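#' Construct an ExpressionCohort
#'
#' @param values numeric matrix, genes x samples, log2-scale expression with
#'   rownames (gene ids) and colnames (sample ids).
#' @param groups character vector (or factor), one group name per sample, in
#'   column order of \code{values}; alternatively a named vector keyed by
#'   sample id.
#' @param control_group character(1), which group is the control.
#' @param cancer_group_order optional character vector fixing the reporting
#'   order of the non-control groups (defines the 0-based group indices of
#'   membership reports). Default: order of first appearance in \code{groups}.
#'
#' @return A validated \linkS4class{ExpressionCohort}.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' co <- ExpressionCohort(m, c("tum", "tum", "ctl", "ctl"), "ctl")
#' cancerGroups(co)
#' @export
ExpressionCohort <- function(values, groups, control_group,
                             cancer_group_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(values), names(groups))
    if (length(miss)) {
      stop(sprintf("sample(s) missing a group assignment: %s",
                   paste(miss, collapse = ", ")))
    }
    extra <- setdiff(names(groups), colnames(values))
    if (length(extra)) {
      stop(sprintf("group assignment for unknown sample(s): %s",
                   paste(extra, collapse = ", ")))
    }
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values)) {
    stop("one group per sample column is required")
  }
  if (is.null(cancer_group_order)) {
    cancer_group_order <- setdiff(unique(groups), control_group)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values),
    colData = S4Vectors::DataFrame(group = groups, row.names = colnames(values))
  )
  new("ExpressionCohort", se,
      controlGroup = as.character(control_group),
      cancerGroups = as.character(cancer_group_order))
}

#' Accessors for ExpressionCohort
#'
#' \code{controlGroup}: name of the control group. \code{cancerGroups}:
#' ordered non-control group names (index i of the membership report is
#' \code{cancerGroups(x)[i + 1]}). \code{sampleGroups}: named character
#' vector sample id -> group. \code{exprValues}: the log2 expression matrix.
#' \code{geneIds}: gene identifiers.
#'
#' @param x an \linkS4class{ExpressionCohort}.
#' @name ExpressionCohort-accessors
#' @aliases controlGroup cancerGroups sampleGroups exprValues geneIds
NULL

#' @rdname ExpressionCohort-accessors
#' @export
setMethod("controlGroup", "ExpressionCohort", function(x) x@controlGroup)

#' @rdname ExpressionCohort-accessors
#' @export
setMethod("cancerGroups", "ExpressionCohort", function(x) x@cancerGroups)

#' @rdname ExpressionCohort-accessors
#' @export
setMethod("sampleGroups", "ExpressionCohort", function(x) {
  g <- as.character(x@colData$group)
  names(g) <- colnames(x)
  g
})

#' @rdname ExpressionCohort-accessors
#' @export
setMethod("exprValues", "ExpressionCohort", function(x) {
  SummarizedExperiment::assay(x, "log2expr")
})

#' @rdname ExpressionCohort-accessors
#' @export
setMethod("geneIds", "ExpressionCohort", function(x) rownames(x))

#' All group names of a cohort, cancer groups first, control last
#' @param x an ExpressionCohort
#' @return character vector of group names
#' @export
allGroups <- function(x) c(cancerGroups(x), controlGroup(x))

setMethod("show", "ExpressionCohort", function(object) {
  sizes <- table(sampleGroups(object))
  cat(sprintf("ExpressionCohort: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  control group: %s (n = %d)\n", controlGroup(object),
              sizes[[controlGroup(object)]]))
  cg <- cancerGroups(object)
  cat(sprintf("  cancer groups (index order): %s\n",
              paste(sprintf("%s[%d]=%d", cg, seq_along(cg) - 1L,
                            as.integer(sizes[cg])), collapse = " ")))
})

#' Accessors for SelectionList
#'
#' \code{selectedGenes}: the selected gene identifiers in rank order.
#'
#' @rdname SelectionList-accessors
#' @name SelectionList-accessors
#' @param x a \linkS4class{SelectionList}
#' @aliases selectedGenes
#' @export
setMethod("selectedGenes", "SelectionList", function(x) x@genes)

setMethod("show", "SelectionList", function(object) {
  cat(sprintf("SelectionList: %s / %s, fraction %g -> k = %d of %d rankable\n",
              object@group, object@criterion, object@fraction, object@k,
              object@nRankable))
  head_genes <- utils::head(object@genes, 8L)
  cat("  ", paste(head_genes, collapse = " "),
      if (object@k > 8L) "..." else "", "\n")
})

#' Accessors for RelativeExpression
#'
#' \code{relMeans}: per-group gene means of the selected set.
#' \code{relRanks}: their within-group ranks (1 = lowest mean).
#'
#' @rdname RelativeExpression-accessors
#' @name RelativeExpression-accessors
#' @param x a \linkS4class{RelativeExpression}
#' @aliases relMeans relRanks
#' @export
setMethod("relMeans", "RelativeExpression", function(x) x@means)

#' @rdname RelativeExpression-accessors
#' @export
setMethod("relRanks", "RelativeExpression", function(x) x@ranks)

setMethod("show", "RelativeExpression", function(object) {
  cat(sprintf("RelativeExpression: %d genes x %d groups (control: %s)\n",
              nrow(object@means), ncol(object@means), object@controlGroup))
})

setMethod("show", "GeneDendrogram", function(object) {
  cat(sprintf("GeneDendrogram: %d leaves, %s linkage, height range [%g, %g]\n",
              length(object@labels), object@linkage,
              min(object@heights), max(object@heights)))
})
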