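.criteria <- c("low_sd", "low_rel_sd", "low_diff", "high_diff")

.criterionStat <- function(criterion) {
  switch(criterion,
         low_sd = "sd",
         low_rel_sd = "rel_sd",
         low_diff = "abs_diff",
         high_diff = "abs_diff",
         stop(sprintf("unknown criterion '%s' (expected one of: %s)",
                      criterion, paste(.criteria, collapse = ", "))))
}

#' Select the extreme fraction of one group's genes under one criterion
#'
#' Ranks the genes of \code{group} by the criterion statistic — ascending
#' for \code{low_sd} (standard deviation), \code{low_rel_sd} (coefficient of
#' variation) and \code{low_diff} (|log2 difference vs control|), descending
#' for \code{high_diff} — and keeps the top \code{k = max(1, floor(fraction
#' * G))} genes, where G counts the genes with a defined statistic.  Ties
#' are broken lexicographically by gene identifier, making the selection
#' fully deterministic.
#'
#' With the screen's default fraction of 0.001 (the "0.1 percent" rule) a
#' cohort of 17814 genes yields k = 17.
#'
#' @param stats data frame from \code{\link{geneGroupStats}}.
#' @param group group name to screen.
#' @param criterion one of \code{"low_sd"}, \code{"low_rel_sd"},
#'   \code{"low_diff"}, \code{"high_diff"}.
#' @param fraction selected proportion in (0, 1] (default 0.001).
#' @return A \linkS4class{SelectionList}.
#' @export
selectFraction <- function(stats, group, criterion, fraction = 0.001) {
  if (!group %in% stats$group) {
    stop(sprintf("unknown group '%s'", group))
  }
  stat_col <- .criterionStat(criterion)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  s <- stats[stats$group == group, ]
  if (criterion == "low_rel_sd") {
    s <- s[!s$rel_sd_undefined, ]
    if (!nrow(s)) {
      stop("criterion 'low_rel_sd': all genes flagged undefined for this group")
    }
  }
  G <- nrow(s)
  k <- selectionK(G, fraction)
  decreasing <- criterion == "high_diff"
  ord <- order(s[[stat_col]], s$gene_id, method = "radix",
               decreasing = c(decreasing, FALSE))
  new("SelectionList", group = group, criterion = criterion,
      fraction = fraction, k = k,
      genes = s$gene_id[ord][seq_len(k)], nRankable = as.integer(G))
}

#' Selection size under the fraction rule
#'
#' \code{k = max(1, floor(fraction * G))}: at least one gene is always
#' selected; otherwise the count is the floor of the requested proportion.
#'
#' @param G number of rankable genes.
#' @param fraction proportion in (0, 1].
#' @return integer selection size.
#' @examples
#' selectionK(17814, 0.001)  # 17
#' selectionK(500, 0.001)    # 1
#' @export
selectionK <- function(G, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  max(1L, as.integer(floor(fraction * G + 1e-9)))
}

#' Intersect per-group selections into a gene membership table
#'
#' Given one \linkS4class{SelectionList} per cancer group, all under the
#' same criterion, lists for every gene the ascending 0-based indices of the
#' groups in which it was selected (index = position in the canonical
#' cancer-group order) and its repeat count.  The table is sorted by
#' descending repeat count, then gene identifier.
#'
#' @param selections list of \linkS4class{SelectionList}, one per cancer
#'   group.
#' @param cancer_groups canonical cancer-group order defining the indices;
#'   default: the groups of \code{selections} in the order given.
#' @return data frame with columns \code{gene_id}, \code{group_indices}
#'   (space-separated ascending 0-based indices) and \code{repeat_count}.
#' @export
buildMembership <- function(selections,
                            cancer_groups = vapply(selections, function(s) s@group,
                                                   character(1L))) {
  stopifnot(length(selections) >= 1L)
  crit <- unique(vapply(selections, function(s) s@criterion, character(1L)))
  if (length(crit) != 1L) {
    stop(sprintf("selections mix criteria: %s", paste(crit, collapse = ", ")))
  }
  sel_groups <- vapply(selections, function(s) s@group, character(1L))
  if (!setequal(sel_groups, cancer_groups) || anyDuplicated(sel_groups)) {
    stop("exactly one selection per cancer group is required")
  }
  hits <- lapply(selections, function(s) {
    data.frame(gene_id = s@genes,
               idx = match(s@group, cancer_groups) - 1L)
  })
  long <- do.call(rbind, hits)
  by_gene <- split(long$idx, long$gene_id)
  out <- data.frame(
    gene_id = names(by_gene),
    group_indices = vapply(by_gene, function(i) paste(sort(i), collapse = " "),
                           character(1L)),
    repeat_count = vapply(by_gene, length, integer(1L)),
    row.names = NULL
  )
  out <- out[order(-out$repeat_count, out$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

membershipGroups <- function(members, cancer_groups) {
  lapply(strsplit(members$group_indices, " ", fixed = TRUE),
         function(i) cancer_groups[as.integer(i) + 1L])
}

#' Build the stable/flexible gene category tables
#'
#' Combines the per-criterion membership tables into the screen's output
#' categories:
#' \describe{
#'   \item{flexible_low_diff}{genes whose expression difference vs control is
#'     among the lowest in at least \code{min_repeat} cancer groups, with
#'     the group names.}
#'   \item{stable_variance}{genes with low-SD membership in every cancer
#'     group.}
#'   \item{stable_low_diff_low_sd}{stable-variance genes that additionally
#'     show low difference in at least \code{min_repeat} groups, annotated
#'     with those groups.}
#'   \item{high_diff_low_sd}{per group, genes in both the high-difference
#'     and the low-SD selection; genes found in more than one group are
#'     flagged common.}
#'   \item{control_low_sd}{the low-SD selection within the control group,
#'     carried through.}
#' }
#' Stable genes are annotated with whether they also sit in the control
#' low-SD list.  Output is invariant to the row order of the inputs.
#'
#' @param low_diff_members membership table built from \code{low_diff}
#'   selections (\code{\link{buildMembership}}).
#' @param low_sd_members membership table built from \code{low_sd}
#'   selections.
#' @param control_low_sd \linkS4class{SelectionList} of the control group
#'   under \code{low_sd}.
#' @param high_diff_low_sd_per_group named list (by cancer group) of gene
#'   sets in both the high-difference and low-SD selections of that group.
#' @param cancer_groups canonical cancer-group order.
#' @param min_repeat minimum number of groups for the low-difference
#'   categories, in 2..number of cancer groups (default 4).
#' @return named list of data frames (see Details).
#' @export
categorize <- function(low_diff_members, low_sd_members, control_low_sd,
                       high_diff_low_sd_per_group, cancer_groups,
                       min_repeat = 4L) {
  ncg <- length(cancer_groups)
  if (min_repeat < 2L || min_repeat > ncg) {
    stop(sprintf("min_repeat must lie in [2, %d]", ncg))
  }
  ctl_set <- selectedGenes(control_low_sd)

  ld <- low_diff_members[order(-low_diff_members$repeat_count,
                               low_diff_members$gene_id, method = "radix"), ]
  flex <- ld[ld$repeat_count >= min_repeat, ]
  flexible_low_diff <- data.frame(
    gene_id = flex$gene_id,
    n_groups = flex$repeat_count,
    groups = vapply(membershipGroups(flex, cancer_groups),
                    paste, character(1L), collapse = ","),
    row.names = NULL
  )

  sv <- low_sd_members[low_sd_members$repeat_count == ncg, ]
  sv <- sv[order(sv$gene_id, method = "radix"), ]
  stable_variance <- data.frame(
    gene_id = sv$gene_id,
    in_control_low_sd = sv$gene_id %in% ctl_set,
    row.names = NULL
  )

  both <- flex[flex$gene_id %in% sv$gene_id, ]
  both <- both[order(both$gene_id, method = "radix"), ]
  stable_low_diff_low_sd <- data.frame(
    gene_id = both$gene_id,
    n_low_diff_groups = both$repeat_count,
    low_diff_groups = vapply(membershipGroups(both, cancer_groups),
                             paste, character(1L), collapse = ","),
    in_control_low_sd = both$gene_id %in% ctl_set,
    row.names = NULL
  )

  hd_long <- do.call(rbind, lapply(cancer_groups, function(g) {
    genes <- sort(unique(high_diff_low_sd_per_group[[g]]))
    if (!length(genes)) return(NULL)
    data.frame(group = g, gene_id = genes, row.names = NULL)
  }))
  if (is.null(hd_long)) {
    hd_long <- data.frame(group = character(), gene_id = character(),
                          is_common = logical())
  } else {
    counts <- table(hd_long$gene_id)
    hd_long$is_common <- counts[hd_long$gene_id] >= 2L
    hd_long$is_common <- as.logical(hd_long$is_common)
  }

  list(
    flexible_low_diff = flexible_low_diff,
    stable_variance = stable_variance,
    stable_low_diff_low_sd = stable_low_diff_low_sd,
    high_diff_low_sd = hd_long,
    control_low_sd = data.frame(gene_id = sort(ctl_set))
  )
}
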