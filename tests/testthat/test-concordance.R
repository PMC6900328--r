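test_that("within-group ranks order the selected genes by mean", {
  cg <- c("x", "y")
  means <- matrix(c(3, 3, 3,
                    5, 5, 5), 2, 3, byrow = TRUE,
                  dimnames = list(c("A", "B"), c(cg, "control")))
  rel <- rel_from_means(means, cg)
  expect_true(all(relRanks(rel)["A", ] == 1L))
  expect_true(all(relRanks(rel)["B", ] == 2L))

  single <- rel_from_means(means["A", , drop = FALSE], cg)
  expect_true(all(relRanks(single) == 1L))

  # oracle comparison: ranks equal per-column sorting
  m3 <- withr::with_seed(12, matrix(rnorm(21, 8), 7, 3,
        dimnames = list(sprintf("G%d", 1:7), c(cg, "control"))))
  rel3 <- rel_from_means(m3, cg)
  for (g in colnames(m3)) {
    expect_identical(relRanks(rel3)[, g],
                     setNames(rank(m3[, g], ties.method = "first"),
                              rownames(m3)))
  }

  st_missing <- data.frame(gene_id = "A", group = "x", n = 5L, mean = 1,
                           sd = 1, rel_sd = 1, rel_sd_undefined = FALSE,
                           diff = 0, fold_ratio = 1, abs_diff = 0)
  expect_error(relativeExpression(st_missing, c("A", "B"), "x", "control"),
               "without statistics")
})

test_that("consistency calls follow the all-groups rank rule", {
  cg <- paste0("t", 1:6)
  withr::with_seed(3, {
    means <- matrix(rnorm(13 * 7, 8), 13, 7,
                    dimnames = list(sprintf("G%02d", 1:13), c(cg, "control")))
  })
  means["G01", cg] <- 2          # far below everything in all cancer groups
  means["G13", cg] <- 15         # far above
  means["G02", cg] <- c(15, 15, 15, 15, 15, 2)  # high in five, low in one
  rel <- rel_from_means(means, cg)
  calls <- consistencyCalls(rel)
  expect_identical(calls$call[calls$gene_id == "G01"], "consistent_low")
  expect_identical(calls$call[calls$gene_id == "G13"], "consistent_high")
  expect_identical(calls$call[calls$gene_id == "G02"], "mixed")
  # rule boundary: rank <= floor(m/2) in all six, m = 13 -> rank <= 6
  ranks <- relRanks(rel)[, cg]
  low_rule <- rowSums(ranks <= 6) == 6
  expect_identical(calls$call == "consistent_low",
                   unname(low_rule[calls$gene_id]))

  # the control column never enters the call
  means2 <- means
  means2[, "control"] <- rev(means2[, "control"])
  calls2 <- consistencyCalls(rel_from_means(means2, cg))
  expect_identical(calls$call, calls2$call)
})

test_that("consistency calls are rank-invariant under monotone transforms", {
  cg <- c("p", "q", "r", "s")
  withr::with_seed(8, {
    means <- matrix(rnorm(30, 8), 6, 4 + 1,
                    dimnames = list(sprintf("G%d", 1:6), c(cg, "control")))
  })
  a <- consistencyCalls(rel_from_means(means, cg))
  warped <- means
  for (g in colnames(means)) warped[, g] <- exp(means[, g] / 3) + 1
  b <- consistencyCalls(rel_from_means(warped, cg))
  expect_identical(a, b)
})

test_that("clustering reproduces worked small examples", {
  cg <- "x"
  two <- matrix(c(0, 0, 4, 4), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("x", "control")))
  d2 <- clusterGenes(rel_from_means(two, cg))
  expect_equal(d2@heights, sqrt(32))

  # 1-d profiles 0, 1, 3: merge (A, B) at 1, then C joins at mean(3, 2) = 2.5
  st <- data.frame(gene_id = c("A", "B", "C"), group = "x", n = 3L,
                   mean = c(0, 1, 3), sd = 0.1, rel_sd = 0.1,
                   rel_sd_undefined = FALSE, diff = 0, fold_ratio = 1,
                   abs_diff = 0)
  rel <- relativeExpression(st, c("A", "B", "C"), character(0), "x")
  d3 <- clusterGenes(rel)
  expect_equal(d3@heights, c(1, 2.5))
  expect_identical(d3@merges[1, ], c(-2L, -1L))

  ident <- matrix(c(5, 5, 5, 5), 2, 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("x", "control")))
  d0 <- clusterGenes(rel_from_means(ident, cg))
  expect_equal(d0@heights, 0)
})

test_that("average linkage agrees with hclust and stays monotone", {
  for (s in 1:50) {
    m <- withr::with_seed(300 + s, {
      n <- sample(3:8, 1)
      matrix(rnorm(n * 4, 8), n, 4,
             dimnames = list(sprintf("g%02d", seq_len(n)),
                             c("a", "b", "c", "control")))
    })
    rel <- rel_from_means(m, c("a", "b", "c"))
    dend <- clusterGenes(rel)
    expect_true(all(diff(dend@heights) >= -1e-10))
    hc <- hclust(dist(m), method = "average")
    expect_same_tree(dend, hc)
  }
})

test_that("single and complete linkage are available and correct", {
  m <- withr::with_seed(9, matrix(rnorm(24, 8), 6, 4,
        dimnames = list(sprintf("g%d", 1:6), c("a", "b", "c", "control"))))
  rel <- rel_from_means(m, c("a", "b", "c"))
  for (lk in c("single", "complete")) {
    dend <- clusterGenes(rel, linkage = lk)
    expect_same_tree(dend, hclust(dist(m), method = lk))
  }
})

test_that("row scaling and degenerate inputs are handled", {
  m <- withr::with_seed(14, matrix(rnorm(12, 8), 3, 4,
        dimnames = list(c("A", "B", "C"), c("a", "b", "c", "control"))))
  rel <- rel_from_means(m, c("a", "b", "c"))
  ds <- clusterGenes(rel, scale_rows = TRUE)
  expect_same_tree(ds, hclust(dist(t(scale(t(m)))), method = "average"))

  flat <- m
  flat["A", ] <- 5  # zero-variance profile cannot be row-scaled
  expect_error(clusterGenes(rel_from_means(flat, c("a", "b", "c")),
                            scale_rows = TRUE), "non-finite")
})

test_that("the Newick export is a valid ultrametric tree over the genes", {
  m <- withr::with_seed(6, matrix(rnorm(20, 8), 5, 4,
        dimnames = list(sprintf("G%d", 1:5), c("a", "b", "c", "control"))))
  rel <- rel_from_means(m, c("a", "b", "c"))
  dend <- clusterGenes(rel)
  p <- withr::local_tempfile(fileext = ".nwk")
  writeDendrogramNewick(dend, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, rownames(m))
  expect_true(ape::is.ultrametric(tree, tol = 1e-8))
})
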