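#' Specification of a synthetic multi-group expression cohort
#'
#' Defines the generative model used to emulate a pan-cancer expression
#' study: several cancer groups and one control group share per-gene
#' baseline means, cancer groups sit systematically above the control on the
#' log2 scale, and three planted gene classes carry the structure the
#' screening pipeline is meant to find.
#'
#' Gene classes:
#' \describe{
#'   \item{background}{group mean = baseline + \code{cancer_mean_shift} +
#'     per-(gene, group) jitter of SD \code{background_shift_sd}; full noise.}
#'   \item{stable_variance}{mean structure as background, but the gene's
#'     noise SD is multiplied by \code{stable_sd_factor} in every group.}
#'   \item{flexible}{group mean equals the control baseline exactly in a
#'     drawn subset of 4 or 5 cancer groups (uniform over all such subsets)
#'     and is shifted by \code{flex_shift} elsewhere; full noise.}
#'   \item{shifted_stable}{shifted by \code{shift_effect} in every cancer
#'     group, with noise SD multiplied by \code{stable_sd_factor}.}
#' }
#'
#' Each gene draws one intrinsic noise SD from
#' \code{Normal(noise_sd_center, noise_sd_spread)} truncated below at 0.05;
#' that SD is shared by all groups (scaled by \code{control_sd_scale} in the
#' control group), so low-variance genes are low-variance in every cohort.
#'
#' @param n_genes number of genes (default 2000).
#' @param group_sizes named integer vector of samples per group, control
#'   included. Default mirrors a published pan-cancer design: colon 174,
#'   ovarian 255, breast 621, lung 32, brain 694, renal 72, control 48
#'   (1896 samples in total).
#' @param control_group name of the control group (default "control").
#' @param baseline_mean_center,baseline_mean_spread normal law of per-gene
#'   baseline means, log2 units (defaults 8.0, 2.0).
#' @param noise_sd_center,noise_sd_spread normal law of per-gene noise SDs,
#'   log2 units (defaults 0.65, 0.15 — the scale observed in tumor
#'   microarray cohorts, average gene SDs around 0.6-0.72).
#' @param n_stable_variance,n_flexible,n_shifted_stable planted class sizes
#'   (defaults 50, 30, 20).
#' @param stable_sd_factor noise-SD multiplier of the two stable classes
#'   (default 0.1).
#' @param flex_shift log2 shift of flexible genes outside their
#'   control-tracking groups (default 1.5).
#' @param shift_effect log2 shift of shifted-stable genes (default 2.0).
#' @param background_shift_sd SD of the per-(gene, group) mean jitter of
#'   background and stable-variance genes (default 0.3).
#' @param cancer_mean_shift systematic log2 elevation of every cancer group
#'   over control (default 1.0; tumor cohorts show globally larger mean
#'   expression than control).
#' @param control_sd_scale multiplier on the noise SD inside the control
#'   group (default 0.7; the control group shows the lowest average gene SD).
#' @param seed integer RNG seed; identical specs with identical seeds
#'   generate bit-identical cohorts.
#'
#' @return A validated \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(n_genes = 2000L,
                          group_sizes = c(colon = 174L, ovarian = 255L,
                                          breast = 621L, lung = 32L,
                                          brain = 694L, renal = 72L,
                                          control = 48L),
                          control_group = "control",
                          baseline_mean_center = 8.0,
                          baseline_mean_spread = 2.0,
                          noise_sd_center = 0.65,
                          noise_sd_spread = 0.15,
                          n_stable_variance = 50L,
                          n_flexible = 30L,
                          n_shifted_stable = 20L,
                          stable_sd_factor = 0.1,
                          flex_shift = 1.5,
                          shift_effect = 2.0,
                          background_shift_sd = 0.3,
                          cancer_mean_shift = 1.0,
                          control_sd_scale = 0.7,
                          seed = 1L) {
  sizes <- as.integer(group_sizes)
  names(sizes) <- names(group_sizes)
  new("SyntheticSpec",
      nGenes = as.integer(n_genes),
      groupSizes = sizes,
      controlGroup = control_group,
      cancerGroupOrder = setdiff(names(sizes), control_group),
      baselineMeanCenter = baseline_mean_center,
      baselineMeanSpread = baseline_mean_spread,
      noiseSdCenter = noise_sd_center,
      noiseSdSpread = noise_sd_spread,
      nStableVariance = as.integer(n_stable_variance),
      nFlexible = as.integer(n_flexible),
      nShiftedStable = as.integer(n_shifted_stable),
      stableSdFactor = stable_sd_factor,
      flexShift = flex_shift,
      shiftEffect = shift_effect,
      backgroundShiftSd = background_shift_sd,
      cancerMeanShift = cancer_mean_shift,
      controlSdScale = control_sd_scale,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticSpec: %d genes, %d samples (%d groups), seed %d\n",
    "  planted: %d stable_variance, %d flexible, %d shifted_stable\n"),
    object@nGenes, sum(object@groupSizes), length(object@groupSizes),
    object@seed, object@nStableVariance, object@nFlexible,
    object@nShiftedStable))
})

#' Generate a synthetic cohort with planted gene classes and truth labels
#'
#' Samples a cohort under the model described in \code{\link{syntheticSpec}}.
#' Planted classes are assigned to randomly drawn, non-overlapping gene
#' subsets; everything is driven by the spec's seed, so equal specs give
#' bit-identical results.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A list with components \code{cohort} (an
#'   \linkS4class{ExpressionCohort}) and \code{truth} (a data frame with
#'   columns \code{gene_id}, \code{class}, and \code{tracking_groups} — the
#'   comma-separated control-tracking cancer groups, non-empty only for
#'   flexible genes).
#' @examples
#' sim <- generateCohort(syntheticSpec(n_genes = 100,
#'   group_sizes = c(a = 10, b = 12, control = 8), seed = 7))
#' table(sim$truth$class)
#' @export
generateCohort <- function(spec) {
  methods::validObject(spec)
  withr::with_seed(spec@seed, generateCohortImpl(spec))
}

generateCohortImpl <- function(spec) {
  n <- spec@nGenes
  cg <- spec@cancerGroupOrder
  ncg <- length(cg)
  gene_ids <- sprintf("G%05d", seq_len(n))

  cls <- rep("background", n)
  planted_n <- spec@nStableVariance + spec@nFlexible + spec@nShiftedStable
  idx <- sample.int(n, planted_n)
  i_sv <- idx[seq_len(spec@nStableVariance)]
  i_fx <- idx[spec@nStableVariance + seq_len(spec@nFlexible)]
  i_ss <- idx[spec@nStableVariance + spec@nFlexible + seq_len(spec@nShiftedStable)]
  cls[i_sv] <- "stable_variance"
  cls[i_fx] <- "flexible"
  cls[i_ss] <- "shifted_stable"

  baseline <- stats::rnorm(n, spec@baselineMeanCenter, spec@baselineMeanSpread)
  sigma <- pmax(stats::rnorm(n, spec@noiseSdCenter, spec@noiseSdSpread), 0.05)
  sigma[cls %in% c("stable_variance", "shifted_stable")] <-
    sigma[cls %in% c("stable_variance", "shifted_stable")] * spec@stableSdFactor

  # control-tracking subsets of flexible genes: uniform over all subsets of
  # size 4 or 5 of the cancer groups (sizes weighted by subset counts)
  track <- vector("list", n)
  if (spec@nFlexible > 0L) {
    if (ncg < 4L) stop("flexible genes require at least 4 cancer groups")
    size_opts <- c(4L, 5L)
    size_opts <- size_opts[size_opts <= ncg]
    w <- choose(ncg, size_opts)
    for (i in i_fx) {
      sz <- size_opts[sample.int(length(size_opts), 1L, prob = w)]
      track[[i]] <- sort(sample.int(ncg, sz))
    }
  }

  # per-(gene, group) target means, cancer groups then control
  mu <- matrix(baseline, n, ncg + 1L)
  colnames(mu) <- c(cg, spec@controlGroup)
  for (j in seq_len(ncg)) {
    bg <- cls %in% c("background", "stable_variance")
    mu[bg, j] <- baseline[bg] + spec@cancerMeanShift +
      stats::rnorm(sum(bg), 0, spec@backgroundShiftSd)
    mu[i_ss, j] <- baseline[i_ss] + spec@shiftEffect
    if (length(i_fx)) {
      tracks_j <- vapply(track[i_fx], function(s) j %in% s, logical(1L))
      mu[i_fx[!tracks_j], j] <- baseline[i_fx[!tracks_j]] + spec@flexShift
      # tracking groups keep mu == baseline == control mean
    }
  }

  sizes <- spec@groupSizes[c(cg, spec@controlGroup)]
  values <- matrix(NA_real_, n, sum(sizes))
  sample_ids <- character(sum(sizes))
  groups <- character(sum(sizes))
  off <- 0L
  for (j in seq_along(sizes)) {
    gname <- names(sizes)[j]
    m <- sizes[[j]]
    sd_scale <- if (gname == spec@controlGroup) spec@controlSdScale else 1
    noise <- matrix(stats::rnorm(n * m), n, m) * (sigma * sd_scale)
    values[, off + seq_len(m)] <- mu[, gname] + noise
    sample_ids[off + seq_len(m)] <- sprintf("%s_%03d", gname, seq_len(m))
    groups[off + seq_len(m)] <- gname
    off <- off + m
  }
  dimnames(values) <- list(gene_ids, sample_ids)

  truth <- data.frame(
    gene_id = gene_ids,
    class = cls,
    tracking_groups = vapply(track, function(s) {
      if (is.null(s)) "" else paste(cg[s], collapse = ",")
    }, character(1L))
  )
  cohort <- ExpressionCohort(values, groups, spec@controlGroup,
                             cancer_group_order = cg)
  list(cohort = cohort, truth = truth)
}

#' Score predicted gene sets against planted truth labels
#'
#' For each predicted category, sensitivity is the fraction of planted genes
#' recovered and precision the fraction of predicted genes that were
#' planted.  An empty prediction yields precision 0 with the
#' \code{empty_prediction} flag set.
#'
#' @param truth truth-label data frame from \code{\link{generateCohort}}
#'   (columns \code{gene_id}, \code{class}).
#' @param predicted named list of character vectors of gene ids; names are
#'   truth classes.
#' @return data frame with one row per predicted class: counts,
#'   \code{sensitivity}, \code{precision}, \code{empty_prediction}.
#' @export
evaluateRecovery <- function(truth, predicted) {
  stopifnot(is.data.frame(truth), all(c("gene_id", "class") %in% names(truth)))
  if (!is.list(predicted) || is.null(names(predicted))) {
    stop("'predicted' must be a named list of gene-id vectors")
  }
  bad_class <- setdiff(names(predicted), unique(truth$class))
  if (length(bad_class)) {
    stop(sprintf("predicted class(es) not present in truth: %s",
                 paste(bad_class, collapse = ", ")))
  }
  unknown <- setdiff(unlist(predicted, use.names = FALSE), truth$gene_id)
  if (length(unknown)) {
    stop(sprintf("prediction references unknown gene(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  rows <- lapply(names(predicted), function(klass) {
    planted <- truth$gene_id[truth$class == klass]
    pred <- unique(predicted[[klass]])
    hit <- length(intersect(pred, planted))
    data.frame(
      class = klass,
      n_planted = length(planted),
      n_predicted = length(pred),
      n_hit = hit,
      sensitivity = if (length(planted)) hit / length(planted) else NA_real_,
      precision = if (length(pred)) hit / length(pred) else 0,
      empty_prediction = length(pred) == 0L
    )
  })
  do.call(rbind, rows)
}
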