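#' Configuration of the end-to-end screening pipeline
#'
#' Either \code{matrix_path} + \code{groups_path} (load a cohort from disk)
#' or \code{synthetic_spec} (generate one, truth labels included) must be
#' given.
#'
#' @param out_dir output directory (created if absent).
#' @param matrix_path,groups_path input cohort files (see
#'   \code{\link{readCohort}}).
#' @param synthetic_spec a \linkS4class{SyntheticSpec}; when given, the
#'   cohort is simulated and recovery against the planted truth is scored.
#' @param fraction selected proportion for the difference screens
#'   (default 0.001, the 0.1 percent rule).
#' @param sd_fraction proportion for the low-SD screens; defaults to
#'   \code{fraction}.
#' @param high_fraction proportion for the high-difference screen; defaults
#'   to \code{fraction}.
#' @param min_repeat minimum group count for the low-difference categories
#'   (default 4).
#' @param linkage clustering linkage (default "average").
#' @param scale_rows center/scale gene profiles before clustering
#'   (default FALSE).
#' @param low_frac consistency-call rank threshold (default 0.5).
#' @param quiet suppress progress messages (default TRUE).
#' @return a validated config list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir,
                           matrix_path = NULL, groups_path = NULL,
                           synthetic_spec = NULL,
                           fraction = 0.001, sd_fraction = NULL,
                           high_fraction = NULL, min_repeat = 4L,
                           linkage = "average", scale_rows = FALSE,
                           low_frac = 0.5, quiet = TRUE) {
  if (is.null(synthetic_spec) && (is.null(matrix_path) || is.null(groups_path))) {
    stop("either synthetic_spec or matrix_path + groups_path must be given")
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  cfg <- list(out_dir = out_dir, matrix_path = matrix_path,
              groups_path = groups_path, synthetic_spec = synthetic_spec,
              fraction = fraction,
              sd_fraction = sd_fraction %||% fraction,
              high_fraction = high_fraction %||% fraction,
              min_repeat = as.integer(min_repeat),
              linkage = linkage, scale_rows = scale_rows,
              low_frac = low_frac, quiet = quiet)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full screening pipeline
#'
#' Stages: input (load or simulate the cohort), stats (per-gene per-group
#' descriptives + group summaries with pooled Mann-Whitney tests), screen
#' (fraction selections per criterion and group, membership intersection,
#' category tables, plain-text membership reports), report (relative
#' expression, consistency calls, average-linkage dendrogram with Newick
#' export over the stable gene set), recover (when a synthetic truth is
#' available, sensitivity/precision per planted class), and a YAML run
#' manifest with an md5 hash of every output file.  Identical configuration
#' and seed give identical hashes.  A failing stage removes the files it
#' already wrote and signals an error prefixed with the stage name.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the manifest list (config summary, per-file md5
#'   hashes, per-stage gene counts).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log <- function(fmt, ...) if (!config$quiet) message(sprintf(fmt, ...))
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage[%s]: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  counts <- list()

  ## -- input ----------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(config$synthetic_spec)) {
      sim <- generateCohort(config$synthetic_spec)
      emit("cohort_matrix.tsv", function(p) {
        writeCohort(sim$cohort, p, file.path(config$out_dir, "cohort_groups.tsv"))
        written <<- c(written, file.path(config$out_dir, "cohort_groups.tsv"))
      })
      emit("truth_labels.tsv", function(p) writeTable(sim$truth, p))
      sim
    } else {
      if (!file.exists(config$matrix_path) || !file.exists(config$groups_path)) {
        stop("input file(s) not found")
      }
      list(cohort = readCohort(config$matrix_path, config$groups_path),
           truth = NULL)
    }
  })
  cohort <- inp$cohort
  cg <- cancerGroups(cohort)
  log("input: %d genes, %d samples, %d cancer groups",
      nrow(cohort), ncol(cohort), length(cg))

  ## -- stats ----------------------------------------------------------
  st <- stage("stats", {
    stats <- geneGroupStats(cohort)
    summaries <- groupSummaries(stats, cohort)
    emit("gene_group_stats.tsv", function(p) writeTable(stats, p))
    emit("group_summaries.tsv", function(p) writeTable(summaries, p))
    list(stats = stats, summaries = summaries)
  })

  ## -- screen ---------------------------------------------------------
  sc <- stage("screen", {
    frac_of <- function(criterion) {
      switch(criterion, low_sd = config$sd_fraction,
             high_diff = config$high_fraction, config$fraction)
    }
    sel <- list()
    for (crit in .criteria) {
      sel[[crit]] <- lapply(cg, function(g) {
        selectFraction(st$stats, g, crit, frac_of(crit))
      })
    }
    sel_tab <- do.call(rbind, lapply(unlist(sel, recursive = FALSE), function(s) {
      data.frame(group = s@group, criterion = s@criterion,
                 fraction = s@fraction, k = s@k, rank = seq_len(s@k),
                 gene_id = s@genes)
    }))
    emit("selections.tsv", function(p) writeTable(sel_tab, p))

    members <- list(
      low_diff = buildMembership(sel$low_diff, cg),
      low_sd = buildMembership(sel$low_sd, cg),
      low_rel_sd = buildMembership(sel$low_rel_sd, cg)
    )
    for (crit in names(members)) {
      emit(sprintf("membership_%s.tsv", crit), function(p) {
        writeTable(members[[crit]], p)
      })
      emit(sprintf("membership_%s_report.txt", crit), function(p) {
        writeLines(formatMembershipReport(members[[crit]], cg), p)
      })
    }

    control_low_sd <- selectFraction(st$stats, controlGroup(cohort), "low_sd",
                                     config$sd_fraction)
    hd_low_sd <- lapply(seq_along(cg), function(i) {
      intersect(selectedGenes(sel$high_diff[[i]]),
                selectedGenes(sel$low_sd[[i]]))
    })
    names(hd_low_sd) <- cg

    cats <- categorize(members$low_diff, members$low_sd, control_low_sd,
                       hd_low_sd, cg, config$min_repeat)
    for (nm in names(cats)) {
      emit(sprintf("category_%s.tsv", nm), function(p) writeTable(cats[[nm]], p))
    }
    counts$selected_per_group <- sel$low_sd[[1L]]@k
    counts$flexible_low_diff <- nrow(cats$flexible_low_diff)
    counts$stable_variance <- nrow(cats$stable_variance)
    counts$stable_low_diff_low_sd <- nrow(cats$stable_low_diff_low_sd)
    log("screen: %d flexible, %d stable-variance, %d stable genes",
        counts$flexible_low_diff, counts$stable_variance,
        counts$stable_low_diff_low_sd)
    list(selections = sel, members = members, categories = cats,
         control_low_sd = control_low_sd)
  })

  ## -- report ---------------------------------------------------------
  stage("report", {
    genes <- sc$categories$stable_low_diff_low_sd$gene_id
    if (length(genes) < 2L) genes <- sc$categories$stable_variance$gene_id
    if (length(genes) >= 2L) {
      rel <- relativeExpression(st$stats, genes, cg, controlGroup(cohort))
      rel_tab <- data.frame(gene_id = rownames(relMeans(rel)),
                            relMeans(rel), check.names = FALSE)
      emit("relative_expression_means.tsv", function(p) writeTable(rel_tab, p))
      rank_tab <- data.frame(gene_id = rownames(relRanks(rel)),
                             relRanks(rel), check.names = FALSE)
      emit("relative_expression_ranks.tsv", function(p) writeTable(rank_tab, p))
      calls <- consistencyCalls(rel, config$low_frac)
      emit("consistency_calls.tsv", function(p) writeTable(calls, p))
      dend <- clusterGenes(rel, config$scale_rows, config$linkage)
      emit("dendrogram.nwk", function(p) writeDendrogramNewick(dend, p))
    } else {
      log("report: fewer than 2 stable genes; concordance outputs skipped")
    }
    counts$concordance_genes <- length(genes)
    NULL
  })

  ## -- recover --------------------------------------------------------
  recovery <- stage("recover", {
    if (is.null(inp$truth)) {
      NULL
    } else {
      hd <- sc$categories$high_diff_low_sd
      # shifted genes show the high-diff/low-SD signature in more than one
      # cancer group (the screen's "common genes"); a single-group hit can be
      # a jitter outlier and does not reclassify a gene
      hd_common <- unique(hd$gene_id[hd$is_common])
      predicted <- list(
        stable_variance = setdiff(sc$categories$stable_variance$gene_id,
                                  hd_common),
        flexible = sc$categories$flexible_low_diff$gene_id,
        shifted_stable = hd_common
      )
      rec <- evaluateRecovery(inp$truth, predicted)
      emit("recovery.tsv", function(p) writeTable(rec, p))
      rec
    }
  })

  ## -- manifest -------------------------------------------------------
  hashes <- as.list(unname(tools::md5sum(written)))
  names(hashes) <- basename(written)
  hashes <- hashes[order(names(hashes), method = "radix")]
  manifest <- list(
    seed = if (!is.null(config$synthetic_spec)) config$synthetic_spec@seed else NA,
    fraction = config$fraction,
    sd_fraction = config$sd_fraction,
    high_fraction = config$high_fraction,
    min_repeat = config$min_repeat,
    linkage = config$linkage,
    counts = counts,
    files = hashes
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(c(manifest, list(recovery = recovery)))
}

#' Format a membership table as the plain-text group-index report
#'
#' One line per gene in table order, \code{"<GENE>: <i1> <i2> ..."} with
#' ascending 0-based group indices, preceded by comment lines mapping each
#' index to its group name.  \code{\link{parseMembershipReport}} inverts it
#' exactly.
#'
#' @param members membership table from \code{\link{buildMembership}}.
#' @param cancer_groups canonical cancer-group order.
#' @return character vector of report lines.
#' @examples
#' df <- data.frame(gene_id = "ABC", group_indices = "0 3",
#'                  repeat_count = 2L)
#' formatMembershipReport(df, c("colon", "ovarian", "breast", "lung"))
#' @export
formatMembershipReport <- function(members, cancer_groups) {
  header <- c("# gene membership across cancer groups",
              sprintf("# index %d = %s", seq_along(cancer_groups) - 1L,
                      cancer_groups))
  c(header, sprintf("%s: %s", members$gene_id, members$group_indices))
}

#' Parse a membership report back into a membership table
#'
#' @param lines character vector of report lines (comment lines starting
#'   with \code{#} are skipped).
#' @return membership data frame (\code{gene_id}, \code{group_indices},
#'   \code{repeat_count}) in report line order.
#' @export
parseMembershipReport <- function(lines) {
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(gene_id = character(), group_indices = character(),
                      repeat_count = integer()))
  }
  mm <- regmatches(body, regexec("^(.*): ([0-9 ]+)$", body))
  bad <- which(vapply(mm, length, integer(1L)) != 3L)
  if (length(bad)) {
    stop(sprintf("unparseable report line: '%s'", body[bad[1L]]))
  }
  data.frame(
    gene_id = vapply(mm, `[`, character(1L), 2L),
    group_indices = vapply(mm, `[`, character(1L), 3L),
    repeat_count = lengths(strsplit(vapply(mm, `[`, character(1L), 3L), " ",
                                    fixed = TRUE)),
    row.names = NULL
  )
}
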