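test_that("the selection size follows the floor rule with a minimum of 1", {
  expect_identical(selectionK(17814, 0.001), 17L)
  expect_identical(selectionK(500, 0.001), 1L)
  expect_identical(selectionK(1000, 0.001), 1L)
  expect_identical(selectionK(2000, 0.001), 2L)
  expect_identical(selectionK(10, 1), 10L)
  expect_error(selectionK(100, 0), "fraction")
})

test_that("selection picks the extreme values with lexicographic ties", {
  st <- stats_from_values(list(
    g = list(sd = c(A = 0.3, B = 0.1, C = 0.2),
             diff = c(A = 1, B = -2, C = 0.5))
  ))
  low <- selectFraction(st, "g", "low_sd", fraction = 1 / 3)
  expect_identical(selectedGenes(low), "B")

  tie <- stats_from_values(list(g = list(sd = c(A = 0.1, B = 0.1, C = 0.2))))
  expect_identical(selectedGenes(selectFraction(tie, "g", "low_sd", 1 / 3)),
                   "A")

  hi <- selectFraction(st, "g", "high_diff", fraction = 1 / 3)
  expect_identical(selectedGenes(hi), "B")  # largest |diff|
  lo <- selectFraction(st, "g", "low_diff", fraction = 1 / 3)
  expect_identical(selectedGenes(lo), "C")

  expect_error(selectFraction(st, "nope", "low_sd"), "unknown group")
  expect_error(selectFraction(st, "g", "weird"), "unknown criterion")
})

test_that("an all-undefined coefficient of variation is a hard error", {
  st <- stats_from_values(list(g = list(sd = c(A = 0.1, B = 0.2))))
  st$rel_sd_undefined <- TRUE
  st$rel_sd <- NA_real_
  expect_error(selectFraction(st, "g", "low_rel_sd"), "low_rel_sd")
})

test_that("selection equals the brute-force sort-and-slice oracle", {
  for (s in 1:40) {
    inst <- withr::with_seed(s, {
      G <- sample(10:400, 1)
      list(ids = sprintf("g%04d", sample.int(9999, G)),
           sd = round(rexp(G), sample(1:3, 1)),  # rounding creates ties
           frac = runif(1, 0.005, 0.4))
    })
    st <- stats_from_values(list(x = list(sd = setNames(inst$sd, inst$ids))))
    got <- selectedGenes(selectFraction(st, "x", "low_sd", inst$frac))
    want <- selection_oracle(inst$ids, inst$sd, inst$frac)
    expect_identical(got, want)
  }
})

test_that("growing the fraction never drops a selected gene", {
  st <- stats_from_values(list(x = list(
    sd = withr::with_seed(9, setNames(round(rexp(200), 2),
                                      sprintf("g%03d", 1:200))))))
  prev <- character(0)
  for (f in c(0.01, 0.05, 0.1, 0.3, 0.7, 1)) {
    cur <- selectedGenes(selectFraction(st, "x", "low_sd", f))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

make_selection <- function(group, genes, criterion = "low_sd") {
  new("SelectionList", group = group, criterion = criterion,
      fraction = 0.5, k = length(genes), genes = genes,
      nRankable = 100L)
}

test_that("membership lists ascending group indices per gene", {
  cg <- c("colon", "ovarian", "breast", "lung", "brain", "renal")
  sels <- list(
    make_selection("colon",  c("X", "solo")),
    make_selection("ovarian", c("Y")),
    make_selection("breast", c("X", "Y")),
    make_selection("lung",   c("X")),
    make_selection("brain",  c("X")),
    make_selection("renal",  c("Y"))
  )
  mem <- buildMembership(sels, cg)
  expect_identical(mem$gene_id, c("X", "Y", "solo"))
  expect_identical(mem$group_indices[mem$gene_id == "X"], "0 2 3 4")
  expect_identical(mem$repeat_count[mem$gene_id == "X"], 4L)
  expect_identical(mem$repeat_count[mem$gene_id == "solo"], 1L)
  # sorted by descending repeat count, then gene id
  expect_true(all(diff(mem$repeat_count) <= 0))

  # membership equals the definitional cross-check against the raw selections
  for (i in seq_len(nrow(mem))) {
    in_groups <- which(vapply(sels, function(s) mem$gene_id[i] %in% s@genes,
                              logical(1))) - 1L
    expect_identical(mem$group_indices[i], paste(in_groups, collapse = " "))
  }

  bad <- sels
  bad[[2]] <- make_selection("ovarian", "Y", criterion = "low_diff")
  expect_error(buildMembership(bad, cg), "mix")
})

test_that("categories apply the repeat-count thresholds", {
  cg <- paste0("t", 1:6)
  # low_sd in all six: S1, S2; low_diff in >= 4: S1 (4 groups), F1 (5), F2 (3)
  low_sd <- buildMembership(lapply(cg, function(g) {
    make_selection(g, c("S1", "S2", if (g %in% cg[1:3]) "H1"))
  }), cg)
  low_diff <- buildMembership(lapply(cg, function(g) {
    genes <- c(if (g %in% cg[1:4]) "S1", if (g %in% cg[2:6]) "F1",
               if (g %in% cg[1:3]) "F2", "Z")
    make_selection(g, genes, criterion = "low_diff")
  }), cg)
  ctl <- make_selection("control", c("S2", "Q"))
  hd <- setNames(list("H1", "H1", character(), "S1", character(), character()),
                 cg)

  cats <- categorize(low_diff, low_sd, ctl, hd, cg, min_repeat = 4L)

  expect_setequal(cats$flexible_low_diff$gene_id, c("S1", "F1", "Z"))
  expect_identical(
    cats$flexible_low_diff$groups[cats$flexible_low_diff$gene_id == "S1"],
    "t1,t2,t3,t4")
  expect_setequal(cats$stable_variance$gene_id, c("S1", "S2"))
  expect_identical(cats$stable_variance$in_control_low_sd,
                   c(FALSE, TRUE))  # S1 not in control list, S2 is
  expect_identical(cats$stable_low_diff_low_sd$gene_id, "S1")
  expect_identical(cats$stable_low_diff_low_sd$n_low_diff_groups, 4L)
  expect_false(cats$stable_low_diff_low_sd$in_control_low_sd)
  # H1 hits two groups -> common; S1 only one
  hd_tab <- cats$high_diff_low_sd
  expect_true(all(hd_tab$is_common[hd_tab$gene_id == "H1"]))
  expect_false(any(hd_tab$is_common[hd_tab$gene_id == "S1"]))
  expect_identical(cats$control_low_sd$gene_id, c("Q", "S2"))

  # min_repeat excludes F2-like genes below the threshold
  expect_false("F2" %in% cats$flexible_low_diff$gene_id)
  expect_error(categorize(low_diff, low_sd, ctl, hd, cg, min_repeat = 1L),
               "min_repeat")
})

test_that("categorize output is invariant to input row order", {
  cg <- paste0("t", 1:6)
  low_sd <- buildMembership(lapply(cg, function(g) {
    make_selection(g, c("S1", "S2"))
  }), cg)
  low_diff <- buildMembership(lapply(cg, function(g) {
    make_selection(g, c("S1", "A", "B"), criterion = "low_diff")
  }), cg)
  ctl <- make_selection("control", "S1")
  hd <- setNames(rep(list(character()), 6), cg)
  a <- categorize(low_diff, low_sd, ctl, hd, cg)
  shuffle <- function(df) df[withr::with_seed(5, sample.int(nrow(df))), ]
  b <- categorize(shuffle(low_diff), shuffle(low_sd), ctl, hd, cg)
  expect_identical(a, b)
})
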