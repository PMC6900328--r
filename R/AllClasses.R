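#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ExpressionCohort: a grouped log2 expression matrix with a control group
#'
#' Container for a genes x samples matrix of log2-scale expression values,
#' a group assignment for every sample, and the designation of exactly one
#' group as the control.  Extends
#' \link[SummarizedExperiment]{SummarizedExperiment}; the single assay is
#' named \code{"log2expr"} and \code{colData()} carries the \code{group}
#' column.  The non-control ("cancer") groups have a fixed reporting order
#' which defines the 0-based group indices used by the membership report.
#'
#' Validity requires: no missing or non-finite values, unique gene and sample
#' identifiers, every sample assigned to exactly one group, exactly one
#' control group, and at least two samples per group (a sample standard
#' deviation needs n >= 2).
#'
#' @slot controlGroup character(1), name of the control group.
#' @slot cancerGroups character, ordered non-control group names; position
#'   (1-based) minus one is the group index used in membership reports.
#' @export
setClass("ExpressionCohort",
  contains = "SummarizedExperiment",
  representation(controlGroup = "character", cancerGroups = "character")
)

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  x <- SummarizedExperiment::assay(object, "log2expr")
  grp <- object@colData$group
  if (is.null(grp)) {
    return("colData must contain a 'group' column")
  }
  grp <- as.character(grp)
  if (any(!is.finite(x))) {
    msg <- c(msg, "expression values contain missing or non-finite entries")
  }
  gid <- rownames(object)
  sid <- colnames(object)
  if (is.null(gid) || anyDuplicated(gid)) {
    dup <- if (is.null(gid)) "<unnamed>" else gid[duplicated(gid)][1L]
    msg <- c(msg, sprintf("duplicate or missing gene identifier: %s", dup))
  }
  if (is.null(sid) || anyDuplicated(sid)) {
    msg <- c(msg, "duplicate or missing sample identifiers")
  }
  if (length(object@controlGroup) != 1L || is.na(object@controlGroup)) {
    msg <- c(msg, "exactly one control group must be designated")
  }
  groups <- unique(grp)
  if (!all(object@controlGroup %in% groups)) {
    msg <- c(msg, sprintf("control group '%s' has no samples", object@controlGroup))
  }
  if (!setequal(object@cancerGroups, setdiff(groups, object@controlGroup)) ||
      anyDuplicated(object@cancerGroups)) {
    msg <- c(msg, "cancerGroups must list each non-control group exactly once")
  }
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    msg <- c(msg, sprintf("group(s) with fewer than 2 samples: %s",
                          paste(small, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Selection of a gene fraction under one screening criterion
#'
#' The result of ranking one group's genes by one statistic and keeping the
#' extreme fraction (bottom fraction for \code{low_sd}, \code{low_rel_sd},
#' \code{low_diff}; top fraction of \code{abs_diff} for \code{high_diff}).
#'
#' @slot group character(1), the group screened.
#' @slot criterion one of \code{"low_sd"}, \code{"low_rel_sd"},
#'   \code{"low_diff"}, \code{"high_diff"}.
#' @slot fraction numeric(1) in (0, 1].
#' @slot k integer(1), number of genes kept: \code{max(1, floor(fraction * G))}
#'   over the \code{G} rankable genes.
#' @slot genes character, selected gene identifiers in rank order.
#' @slot nRankable integer(1), number of genes with a defined statistic.
#' @export
setClass("SelectionList",
  representation(group = "character", criterion = "character",
                 fraction = "numeric", k = "integer",
                 genes = "character", nRankable = "integer")
)

setValidity("SelectionList", function(object) {
  msg <- character()
  if (!object@criterion %in% c("low_sd", "low_rel_sd", "low_diff", "high_diff")) {
    msg <- c(msg, sprintf("unknown criterion '%s'", object@criterion))
  }
  if (object@fraction <= 0 || object@fraction > 1) {
    msg <- c(msg, "fraction must lie in (0, 1]")
  }
  if (length(object@genes) != object@k) {
    msg <- c(msg, "length(genes) must equal k")
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "selected genes must be unique")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic multi-group cohort generator
#'
#' See \code{\link{syntheticSpec}} for field documentation and defaults.
#'
#' @export
setClass("SyntheticSpec",
  representation(
    nGenes = "integer",
    groupSizes = "integer",            # named, includes the control group
    controlGroup = "character",
    cancerGroupOrder = "character",
    baselineMeanCenter = "numeric",
    baselineMeanSpread = "numeric",
    noiseSdCenter = "numeric",
    noiseSdSpread = "numeric",
    nStableVariance = "integer",
    nFlexible = "integer",
    nShiftedStable = "integer",
    stableSdFactor = "numeric",
    flexShift = "numeric",
    shiftEffect = "numeric",
    backgroundShiftSd = "numeric",
    cancerMeanShift = "numeric",
    controlSdScale = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (is.null(names(object@groupSizes)) || anyDuplicated(names(object@groupSizes))) {
    msg <- c(msg, "groupSizes must be uniquely named")
  }
  if (any(object@groupSizes < 2L)) msg <- c(msg, "all group sizes must be >= 2")
  if (!object@controlGroup %in% names(object@groupSizes)) {
    msg <- c(msg, "controlGroup must appear in groupSizes")
  }
  if (!setequal(object@cancerGroupOrder,
                setdiff(names(object@groupSizes), object@controlGroup))) {
    msg <- c(msg, "cancerGroupOrder must list the non-control groups")
  }
  planted <- object@nStableVariance + object@nFlexible + object@nShiftedStable
  if (planted > object@nGenes) {
    msg <- c(msg, "planted gene counts exceed nGenes")
  }
  if (any(c(object@nStableVariance, object@nFlexible, object@nShiftedStable) < 0L)) {
    msg <- c(msg, "planted gene counts must be non-negative")
  }
  pos <- c(baselineMeanSpread = object@baselineMeanSpread,
           noiseSdCenter = object@noiseSdCenter,
           noiseSdSpread = object@noiseSdSpread,
           stableSdFactor = object@stableSdFactor,
           controlSdScale = object@controlSdScale)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    msg <- c(msg, sprintf("parameter(s) must be positive: %s",
                          paste(bad, collapse = ", ")))
  }
  if (object@backgroundShiftSd < 0) msg <- c(msg, "backgroundShiftSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Within-group rank summary of a selected gene set
#'
#' Per-group mean expression of a selected gene set together with the
#' within-group ranks of those means (1 = lowest mean in that group, ties
#' broken by gene identifier).
#'
#' @slot means numeric matrix, genes x groups (cancer groups then control).
#' @slot ranks integer matrix, same dimensions; each column a permutation of
#'   \code{1..m}.
#' @slot cancerGroups character, the non-control group columns.
#' @slot controlGroup character(1).
#' @export
setClass("RelativeExpression",
  representation(means = "matrix", ranks = "matrix",
                 cancerGroups = "character", controlGroup = "character")
)

setValidity("RelativeExpression", function(object) {
  msg <- character()
  if (!identical(dim(object@means), dim(object@ranks))) {
    msg <- c(msg, "means and ranks must have identical dimensions")
  }
  m <- nrow(object@means)
  if (m > 0L && !all(apply(object@ranks, 2L, function(r) setequal(r, seq_len(m))))) {
    msg <- c(msg, "each rank column must be a permutation of 1..m")
  }
  if (length(msg)) msg else TRUE
})

#' Agglomerative clustering result (merge list)
#'
#' Average-linkage hierarchical clustering of gene profiles under Euclidean
#' distance, stored hclust-style: row i of \code{merges} gives the two
#' clusters joined at \code{heights[i]}; negative entries are leaves (indices
#' into \code{labels}), positive entries refer to earlier merges.
#'
#' @slot merges integer matrix, (m-1) x 2.
#' @slot heights numeric, merge heights in Euclidean-distance units,
#'   non-decreasing (average linkage is monotone).
#' @slot labels character, leaf gene identifiers.
#' @slot linkage character(1), one of "average", "single", "complete".
#' @export
setClass("GeneDendrogram",
  representation(merges = "matrix", heights = "numeric",
                 labels = "character", linkage = "character")
)

setValidity("GeneDendrogram", function(object) {
  msg <- character()
  m <- length(object@labels)
  if (nrow(object@merges) != m - 1L) {
    msg <- c(msg, "a dendrogram over m leaves must contain m-1 merges")
  }
  if (length(object@heights) != nrow(object@merges)) {
    msg <- c(msg, "heights must match the number of merges")
  }
  if (is.unsorted(object@heights + 1e-12 * cummax(abs(object@heights)))) {
    # tolerate floating jitter only
    if (any(diff(object@heights) < -1e-8)) {
      msg <- c(msg, "merge heights must be non-decreasing")
    }
  }
  if (length(msg)) msg else TRUE
})
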