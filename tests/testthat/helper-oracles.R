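# Shared fixtures and independent oracles used across the suite.

# a tiny hand-built cohort: 3 genes x 4 samples, 2 groups of 2
toy_cohort <- function() {
  m <- matrix(c(5, 5, 5, 5,
                1, 2, 3, 4,
                6, 6, 5, 5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"),
                              c("S1", "S2", "S3", "S4")))
  ExpressionCohort(m, c("tumor", "tumor", "ctl", "ctl"), "ctl")
}

# a small seeded random cohort with several groups
random_cohort <- function(seed, n_genes = 40,
                          sizes = c(a = 5, b = 6, c = 4, ctl = 5)) {
  withr::with_seed(seed, {
    n <- sum(sizes)
    m <- matrix(rnorm(n_genes * n, mean = 8, sd = 1), n_genes, n,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n))))
    ExpressionCohort(m, rep(names(sizes), sizes), "ctl")
  })
}

# exact two-sided Mann-Whitney p by enumerating every split of the pooled
# values into the two groups (value-level, independent of rank formulas)
mwu_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# Monte-Carlo permutation estimate of the two-sided MWU p-value
mwu_perm_oracle <- function(x, y, n_perm = 40000, seed = 1) {
  withr::with_seed(seed, {
    pooled <- c(x, y)
    n1 <- length(x)
    u_of <- function(idx) {
      a <- pooled[idx]
      b <- pooled[-idx]
      sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
    }
    u_obs <- u_of(seq_len(n1))
    us <- replicate(n_perm, u_of(sample.int(length(pooled), n1)))
    tol <- 1e-9
    min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
  })
}

# hand-rolled normal approximation with tie + continuity correction,
# written directly from the textbook formulas
mwu_normal_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  t <- table(r)
  s2 <- (n1 * n2 / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(s2)
  list(U = u, p = min(1, 2 * min(pnorm(z), 1 - pnorm(z))))
}

# brute-force fraction selection: repeatedly scan for the smallest (or
# largest) remaining statistic, breaking ties by gene id by explicit scan
selection_oracle <- function(gene_ids, stat, fraction, decreasing = FALSE) {
  G <- length(stat)
  k <- max(1L, as.integer(floor(fraction * G + 1e-9)))
  ids <- gene_ids
  vals <- stat
  picked <- character(0)
  for (step in seq_len(k)) {
    target <- if (decreasing) max(vals) else min(vals)
    at <- which(vals == target)
    best <- at[1L]
    for (i in at[-1L]) if (ids[i] < ids[best]) best <- i
    picked <- c(picked, ids[best])
    ids <- ids[-best]
    vals <- vals[-best]
  }
  picked
}

# stats table built directly from named per-group statistic vectors, for
# screening tests that don't need a full cohort; each element of per_group
# is a list with named vectors sd and diff (mean defaults to 1)
stats_from_values <- function(per_group) {
  rows <- lapply(names(per_group), function(g) {
    v <- per_group[[g]]
    ids <- names(v$sd)
    mean <- if (is.null(v$mean)) rep(1, length(ids)) else v$mean
    diff <- if (is.null(v$diff)) rep(0, length(ids)) else v$diff
    data.frame(gene_id = ids, group = g, n = 5L,
               mean = mean, sd = v$sd,
               rel_sd = v$sd / abs(mean),
               rel_sd_undefined = FALSE,
               diff = diff, fold_ratio = 2^diff, abs_diff = abs(diff),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

# random membership table over n cancer groups
random_membership <- function(seed, n_genes = 12, n_groups = 6) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_genes), function(i) {
      k <- sample.int(n_groups, 1)
      idx <- sort(sample.int(n_groups, k) - 1L)
      data.frame(gene_id = sprintf("GENE%02d", i),
                 group_indices = paste(idx, collapse = " "),
                 repeat_count = k)
    })
    out <- do.call(rbind, rows)
    out[order(-out$repeat_count, out$gene_id, method = "radix"), ,
        drop = FALSE]
  })
}

# RelativeExpression built from an explicit gene x group matrix of means
rel_from_means <- function(means, cancer_groups, control = "control") {
  groups <- c(cancer_groups, control)
  st <- do.call(rbind, lapply(groups, function(g) {
    data.frame(gene_id = rownames(means), group = g, n = 5L,
               mean = means[, g], sd = 0.1, rel_sd = 0.1,
               rel_sd_undefined = FALSE, diff = 0, fold_ratio = 1,
               abs_diff = 0, row.names = NULL)
  }))
  relativeExpression(st, rownames(means), cancer_groups, control)
}

# cophenetic comparison of a GeneDendrogram against stats::hclust
expect_same_tree <- function(dend, hc, tol = 1e-9) {
  mine <- stats::cophenetic(dendrogramToHclust(dend))
  ref <- stats::cophenetic(hc)
  expect_equal(as.matrix(mine)[labels(ref), labels(ref)],
               as.matrix(ref), tolerance = tol)
}
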