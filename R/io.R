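#' Read a grouped expression cohort from a matrix file and a groups sidecar
#'
#' The matrix file is TSV or CSV: header row \code{gene_id} + one sample id
#' per column, then one row per gene with its identifier and a real log2
#' expression value per sample.  The groups sidecar has columns
#' \code{sample_id}, \code{group}, \code{is_control} (0/1, exactly one group
#' flagged 1).  The reporting order of the cancer groups is the order in
#' which non-control groups first appear in the sidecar.
#'
#' @param matrix_path path to the expression matrix file.
#' @param groups_path path to the sample-to-group sidecar.
#' @param delim field delimiter; default inferred from the file extension
#'   (\code{.csv} -> comma, otherwise tab).
#'
#' @return A validated \linkS4class{ExpressionCohort}.
#' @seealso \code{\link{writeCohort}} for the inverse.
#' @export
readCohort <- function(matrix_path, groups_path, delim = NULL) {
  dmat <- delim %||% inferDelim(matrix_path)
  dgrp <- delim %||% inferDelim(groups_path)
  raw <- utils::read.table(matrix_path, sep = dmat, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  if (ncol(raw) < 2L) stop("expression matrix must contain at least one sample column")
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop(sprintf("duplicate gene identifier(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !toupper(vals) %in% "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
                 vals[bad[1L, , drop = FALSE]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))

  gtab <- utils::read.table(groups_path, sep = dgrp, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "", quote = "")
  need <- c("sample_id", "group", "is_control")
  if (!all(need %in% colnames(gtab))) {
    stop(sprintf("groups file must contain columns: %s",
                 paste(need, collapse = ", ")))
  }
  miss <- setdiff(colnames(num), gtab$sample_id)
  if (length(miss)) {
    stop(sprintf("sample(s) in matrix absent from groups file: %s",
                 paste(miss, collapse = ", ")))
  }
  extra <- setdiff(gtab$sample_id, colnames(num))
  if (length(extra)) {
    stop(sprintf("sample(s) in groups file absent from matrix: %s",
                 paste(extra, collapse = ", ")))
  }
  ctl <- unique(gtab$group[gtab$is_control == "1"])
  if (length(ctl) != 1L) {
    stop("exactly one group must be flagged is_control = 1")
  }
  order_seen <- unique(gtab$group)
  groups <- gtab$group
  names(groups) <- gtab$sample_id
  ExpressionCohort(num, groups, ctl,
                   cancer_group_order = setdiff(order_seen, ctl))
}

#' Write a cohort back to a matrix file and groups sidecar
#'
#' Inverse of \code{\link{readCohort}}: expression values are written at
#' full precision (15 significant digits) so that a read/write cycle is
#' value-stable.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param matrix_path,groups_path output paths.
#' @param delim delimiter; default inferred from extension.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(cohort, matrix_path, groups_path, delim = NULL) {
  dmat <- delim %||% inferDelim(matrix_path)
  dgrp <- delim %||% inferDelim(groups_path)
  x <- exprValues(cohort)
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = dmat, quote = FALSE,
                     row.names = FALSE)
  grp <- sampleGroups(cohort)
  # sidecar rows grouped so group first-appearance order is the cohort order
  ord <- order(match(grp, allGroups(cohort)), match(names(grp), names(grp)))
  gtab <- data.frame(sample_id = names(grp)[ord], group = grp[ord],
                     is_control = as.integer(grp[ord] == controlGroup(cohort)))
  # keep control-last like allGroups(); readCohort only needs first appearance
  utils::write.table(gtab, groups_path, sep = dgrp, quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, groups_path))
}

#' Write a pipeline result table as TSV
#'
#' All tabular pipeline outputs go through this writer: TSV with a header
#' row, no quoting, identifiers and group names verbatim, numeric columns
#' rounded to 6 significant digits.  Re-reading with \code{\link{readTable}}
#' and writing again reproduces the file byte for byte.
#'
#' @param rows a data frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(signif(out[[j]], 6L), function(v) {
        if (is.na(v)) NA_character_ else as.character(v)
      }, character(1L))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a table written by writeTable
#'
#' @param path input path.
#' @param col_classes optional named vector of column classes passed to
#'   \code{read.delim} (use to pin identifier columns to character when their
#'   values look numeric).
#' @return a data frame.
#' @export
readTable <- function(path, col_classes = NA) {
  utils::read.delim(path, check.names = FALSE, colClasses = col_classes,
                    quote = "", comment.char = "")
}

inferDelim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
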