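#' Relative expression (within-group ranks) of a selected gene set
#'
#' Restricts the per-group gene means to a selected gene set and ranks the
#' genes within each group (1 = lowest mean in that group; ties broken
#' lexicographically by gene identifier).  Columns are the cancer groups in
#' canonical order followed by the control group.
#'
#' @param stats data frame from \code{\link{geneGroupStats}} covering every
#'   selected gene in every group.
#' @param genes character vector of selected gene identifiers.
#' @param cancer_groups canonical cancer-group order.
#' @param control_group control group name.
#' @return A \linkS4class{RelativeExpression}.
#' @export
relativeExpression <- function(stats, genes, cancer_groups, control_group) {
  genes <- sort(unique(genes))
  groups <- c(cancer_groups, control_group)
  means <- matrix(NA_real_, length(genes), length(groups),
                  dimnames = list(genes, groups))
  for (g in groups) {
    s <- stats[stats$group == g, ]
    i <- match(genes, s$gene_id)
    if (anyNA(i)) {
      stop(sprintf("gene(s) without statistics in group '%s': %s", g,
                   paste(genes[is.na(i)], collapse = ", ")))
    }
    means[, g] <- s$mean[i]
  }
  ranks <- apply(means, 2L, function(v) {
    ord <- order(v, genes, method = "radix")
    r <- integer(length(v))
    r[ord] <- seq_along(v)
    r
  })
  ranks <- matrix(as.integer(ranks), nrow(means), ncol(means),
                  dimnames = dimnames(means))
  new("RelativeExpression", means = means, ranks = ranks,
      cancerGroups = cancer_groups, controlGroup = control_group)
}

#' Call consistently low / high genes across the cancer groups
#'
#' A gene is called \code{consistent_low} when its within-group rank lies in
#' the bottom \code{low_frac} of the selected set (rank <= floor(m *
#' low_frac)) in every cancer group, \code{consistent_high} when its rank
#' exceeds \code{ceiling(m * (1 - low_frac))} in every cancer group, and
#' \code{mixed} otherwise.  The control group does not enter the condition;
#' the default threshold is the median (\code{low_frac = 0.5}).
#'
#' @param rel a \linkS4class{RelativeExpression} over m >= 2 genes.
#' @param low_frac rank threshold fraction in (0, 0.5] (default 0.5; use
#'   1/3 for terciles).
#' @return data frame with \code{gene_id}, \code{call} and one rank column
#'   per cancer group, sorted by call then gene identifier.
#' @export
consistencyCalls <- function(rel, low_frac = 0.5) {
  stopifnot(low_frac > 0, low_frac <= 0.5)
  ranks <- relRanks(rel)[, rel@cancerGroups, drop = FALSE]
  m <- nrow(ranks)
  if (m < 2L) stop("consistency calls need at least 2 selected genes")
  low_cut <- floor(m * low_frac)
  high_cut <- ceiling(m * (1 - low_frac))
  low <- rowSums(ranks <= low_cut) == ncol(ranks)
  high <- rowSums(ranks > high_cut) == ncol(ranks)
  call <- ifelse(low, "consistent_low",
                 ifelse(high, "consistent_high", "mixed"))
  out <- data.frame(gene_id = rownames(ranks), call = call, ranks,
                    row.names = NULL, check.names = FALSE)
  out <- out[order(out$call, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agglomerative hierarchical clustering of gene profiles
#'
#' Clusters the selected genes by the Euclidean distance between their
#' per-group mean vectors (all groups, control included) under average
#' linkage (single and complete linkage available).  Fully deterministic:
#' among merge candidates at equal distance, the pair whose lexicographically
#' smallest member identifiers come first is merged.
#'
#' @param rel a \linkS4class{RelativeExpression} over m >= 2 genes.
#' @param scale_rows if TRUE, each gene's profile is centered and scaled to
#'   unit variance before distances are computed (default FALSE).
#' @param linkage "average" (default), "single" or "complete".
#' @return A \linkS4class{GeneDendrogram}; merge heights are checked to be
#'   non-decreasing (guaranteed for average and complete linkage).
#' @examples
#' # three 1-d profiles at 0, 1, 3: merge at 1, then at mean(c(3, 2)) = 2.5
#' @export
clusterGenes <- function(rel, scale_rows = FALSE, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "single", "complete"))
  x <- relMeans(rel)
  if (!all(is.finite(x))) stop("non-finite values in expression profiles")
  if (scale_rows) {
    x <- t(scale(t(x)))
    if (!all(is.finite(x))) {
      stop("row scaling produced non-finite values (constant profile?)")
    }
  }
  m <- nrow(x)
  if (m < 2L) stop("clustering needs at least 2 genes")
  labels <- rownames(x)
  d <- as.matrix(stats::dist(x, method = "euclidean"))

  # active clusters: id (negative leaf / positive merge), members, size,
  # representative = lexicographically smallest member label
  active <- lapply(seq_len(m), function(i) {
    list(id = -i, size = 1L, rep = labels[i])
  })
  dmat <- d
  merges <- matrix(0L, m - 1L, 2L)
  heights <- numeric(m - 1L)
  for (step in seq_len(m - 1L)) {
    nA <- length(active)
    best <- NULL
    for (i in seq_len(nA - 1L)) {
      for (j in seq.int(i + 1L, nA)) {
        dij <- dmat[i, j]
        reps <- sort(c(active[[i]]$rep, active[[j]]$rep), method = "radix")
        cand <- list(i = i, j = j, d = dij, r1 = reps[1L], r2 = reps[2L])
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (cand$r1 < best$r1 ||
              (cand$r1 == best$r1 && cand$r2 < best$r2)))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    si <- active[[i]]$size
    sj <- active[[j]]$size
    ids <- sort(c(active[[i]]$id, active[[j]]$id))
    merges[step, ] <- ids
    heights[step] <- best$d
    if (step == m - 1L) break
    # linkage update against every other cluster
    newd <- vapply(seq_len(nA), function(k) {
      if (k == i || k == j) return(NA_real_)
      switch(linkage,
             average = (si * dmat[i, k] + sj * dmat[j, k]) / (si + sj),
             single = min(dmat[i, k], dmat[j, k]),
             complete = max(dmat[i, k], dmat[j, k]))
    }, numeric(1L))
    keep <- setdiff(seq_len(nA), c(i, j))
    dmat <- dmat[keep, keep, drop = FALSE]
    newrow <- newd[keep]
    dmat <- rbind(cbind(dmat, newrow), c(newrow, 0))
    active <- c(active[keep],
                list(list(id = step,
                          size = si + sj,
                          rep = min(active[[i]]$rep, active[[j]]$rep))))
  }
  if (linkage != "single" && any(diff(heights) < -1e-8)) {
    stop("internal error: merge heights decreased under monotone linkage")
  }
  new("GeneDendrogram", merges = merges, heights = heights,
      labels = labels, linkage = linkage)
}

#' Convert a GeneDendrogram to a base hclust object
#'
#' @param dend a \linkS4class{GeneDendrogram}.
#' @return an object of class \code{hclust}.
#' @export
dendrogramToHclust <- function(dend) {
  m <- length(dend@labels)
  # leaf ordering for plotting: depth-first left-to-right
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(dend@merges[node, 1L]), expand(dend@merges[node, 2L]))
  }
  structure(list(merge = dend@merges,
                 height = dend@heights,
                 order = expand(m - 1L),
                 labels = dend@labels,
                 method = dend@linkage,
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths derive from merge heights (ultrametric tree, as produced
#' by \code{\link[ape]{as.phylo.hclust}}).
#'
#' @param dend a \linkS4class{GeneDendrogram}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDendrogramNewick <- function(dend, path) {
  phy <- ape::as.phylo(dendrogramToHclust(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}
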