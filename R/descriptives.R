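#' Per-gene per-group descriptive statistics
#'
#' For every (gene, group) pair: sample size, mean, sample standard
#' deviation (n - 1 denominator), relative standard deviation (coefficient
#' of variation, sd / |mean|), and the contrast against the control group —
#' \code{diff} = group mean - control mean (the log2 fold change on
#' log2-scale data), \code{fold_ratio} = 2^diff (the linear ratio) and
#' \code{abs_diff} = |diff|.  Control-group rows carry diff = 0 and
#' fold_ratio = 1 by construction.
#'
#' Genes whose group mean is closer to zero than \code{epsilon} get
#' \code{rel_sd_undefined = TRUE} and an NA relative SD; such genes are
#' excluded from relative-SD rankings rather than producing infinities.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param epsilon threshold on |mean| below which the coefficient of
#'   variation is flagged undefined (default 1e-8).
#' @return data frame with columns \code{gene_id}, \code{group}, \code{n},
#'   \code{mean}, \code{sd}, \code{rel_sd}, \code{rel_sd_undefined},
#'   \code{diff}, \code{fold_ratio}, \code{abs_diff}; groups in cohort order
#'   (cancer groups first, control last).
#' @export
geneGroupStats <- function(cohort, epsilon = 1e-8) {
  x <- exprValues(cohort)
  grp <- sampleGroups(cohort)
  groups <- allGroups(cohort)

  per_group <- lapply(groups, function(g) {
    sub <- x[, grp == g, drop = FALSE]
    n <- ncol(sub)
    mu <- rowMeans(sub)
    sdv <- sqrt(rowSums((sub - mu)^2) / (n - 1L))
    list(n = n, mean = mu, sd = sdv)
  })
  names(per_group) <- groups
  ctl_mean <- per_group[[controlGroup(cohort)]]$mean

  rows <- lapply(groups, function(g) {
    s <- per_group[[g]]
    undef <- abs(s$mean) < epsilon
    rel <- ifelse(undef, NA_real_, s$sd / abs(s$mean))
    d <- if (g == controlGroup(cohort)) rep(0, nrow(x)) else s$mean - ctl_mean
    data.frame(gene_id = rownames(x), group = g, n = s$n,
               mean = s$mean, sd = s$sd,
               rel_sd = rel, rel_sd_undefined = undef,
               diff = d, fold_ratio = 2^d, abs_diff = abs(d),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Group-level summaries with pooled Mann-Whitney tests against control
#'
#' Per group: the average over genes of the within-group gene SDs, the SD
#' over genes of the within-group gene means, the average expression, and —
#' for non-control groups — the pooled two-sided Mann-Whitney U comparison
#' of all the group's expression values against all control values.
#'
#' @param stats output of \code{\link{geneGroupStats}} for \code{cohort}.
#' @param cohort the matching \linkS4class{ExpressionCohort}.
#' @return data frame with one row per group (cohort order): \code{group},
#'   \code{is_control}, \code{n_samples}, \code{avg_of_gene_sds},
#'   \code{sd_of_gene_means}, \code{avg_expression}, \code{mwu_u},
#'   \code{mwu_p} (NA for the control row).
#' @export
groupSummaries <- function(stats, cohort) {
  groups <- allGroups(cohort)
  stopifnot(setequal(unique(stats$group), groups))
  grp <- sampleGroups(cohort)
  rows <- lapply(groups, function(g) {
    s <- stats[stats$group == g, ]
    is_ctl <- g == controlGroup(cohort)
    if (is_ctl) {
      u <- p <- NA_real_
    } else {
      mwu <- mannWhitneyVsControl(cohort, g)
      u <- mwu[["U"]]
      p <- mwu[["p"]]
    }
    data.frame(group = g, is_control = is_ctl,
               n_samples = sum(grp == g),
               avg_of_gene_sds = mean(s$sd),
               sd_of_gene_means = stats::sd(s$mean),
               avg_expression = mean(s$mean),
               mwu_u = u, mwu_p = p, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test of two samples.  With both sides at most 20 observations
#' the p-value is exact: from the null U distribution when the pooled values
#' are tie-free, otherwise by full enumeration of all
#' \code{choose(n1 + n2, n1)} group assignments (falling back to the normal
#' approximation when that count exceeds \code{enum_limit}).  Larger samples
#' use the normal approximation with tie correction and continuity
#' correction.  U is reported for the first sample
#' (\code{sum of x ranks - n1(n1+1)/2}).
#'
#' @param x,y numeric vectors.
#' @param enum_limit maximum number of assignments enumerated on the exact
#'   tied path (default 2e5).
#' @return named numeric vector \code{c(U =, p =)}.
#' @examples
#' mannWhitneyU(c(4, 5, 6), c(1, 2, 3))  # U = 9, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, enum_limit = 2e5) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) > 0L, length(y) > 0L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- as.numeric(length(x))
  n2 <- as.numeric(length(y))
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  small <- n1 <= 20L && n2 <= 20L

  if (small && !has_ties) {
    p <- if (u > n1 * n2 / 2) {
      2 * (1 - stats::pwilcox(u - 1, n1, n2))
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    return(c(U = u, p = min(1, p)))
  }
  if (small && has_ties && choose(n1 + n2, n1) <= enum_limit) {
    p <- enumExactP(r, n1, u)
    return(c(U = u, p = p))
  }
  # normal approximation, tie-corrected variance, continuity correction
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(c(U = u, p = 1))  # all pooled values identical
  }
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  c(U = u, p = min(1, p))
}

# Exact two-sided p by enumerating every assignment of the pooled ranks to
# the first group: p = 2 * min(P(U <= u), P(U >= u)), capped at 1.
enumExactP <- function(r, n1, u) {
  combs <- utils::combn(length(r), n1)
  offset <- n1 * (n1 + 1) / 2
  us <- colSums(matrix(r[combs], nrow = n1)) - offset
  tol <- 1e-9
  p_le <- mean(us <= u + tol)
  p_ge <- mean(us >= u - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Pooled Mann-Whitney comparison of one cancer group against control
#'
#' Pools every expression value of the group's samples (all genes) and
#' compares them against all pooled control values, giving one two-sided
#' p-value per cancer group.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param group a non-control group name.
#' @return named numeric vector \code{c(U =, p =)}.
#' @export
mannWhitneyVsControl <- function(cohort, group) {
  if (!group %in% cancerGroups(cohort)) {
    stop(sprintf("'%s' is not a non-control group of the cohort", group))
  }
  x <- exprValues(cohort)
  grp <- sampleGroups(cohort)
  mannWhitneyU(as.vector(x[, grp == group, drop = FALSE]),
               as.vector(x[, grp == controlGroup(cohort), drop = FALSE]))
}
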