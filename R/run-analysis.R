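#' Validate a pair of input tables against a run configuration
#'
#' Asserts that the Ct and quantity tables describe the same samples in the
#' same order with the same replicate counts, that the candidate and target
#' gene sets are disjoint and present in the right tables, that the removal
#' budget leaves at least the 3-gene minimum pool, and that alpha lies in
#' (0, 1).
#'
#' @param ct Ct-scale \linkS4class{ExpressionTable} (candidates + targets).
#' @param quant quantity-scale \linkS4class{ExpressionTable} (candidates).
#' @param candidateGenes ordered candidate reference genes (the HKG pool).
#' @param targetGenes ordered target genes.
#' @param removeRepetitions removal budget r (>= 0).
#' @param alpha significance level in (0, 1).
#' @return \code{TRUE}, invisibly; errors otherwise.
#' @export
validateRun <- function(ct, quant, candidateGenes, targetGenes,
                        removeRepetitions = 0L, alpha = 0.05) {
  stopifnot(is(ct, "ExpressionTable"), is(quant, "ExpressionTable"))
  if (exprScale(ct) != "ct" || exprScale(quant) != "quantity")
    .qcStop("wrong_scale",
            "need one ct-scale and one quantity-scale table, in that order")
  if (!identical(sampleLevels(ct), sampleLevels(quant)) ||
      !identical(replicateCounts(ct), replicateCounts(quant)))
    .qcStop("sample_set_mismatch",
            "sample set mismatch: the two tables must list the same samples in the same order with the same replicate counts")
  if (length(intersect(candidateGenes, targetGenes)))
    .qcStop("gene_overlap",
            sprintf("gene '%s' cannot be both candidate and target",
                    intersect(candidateGenes, targetGenes)[1L]))
  missQ <- setdiff(candidateGenes, geneNames(quant))
  if (length(missQ))
    .qcStop("unknown_gene",
            sprintf("candidate gene missing from quantity table: %s",
                    missQ[1L]), gene = missQ[1L])
  missC <- setdiff(c(candidateGenes, targetGenes), geneNames(ct))
  if (length(missC))
    .qcStop("unknown_gene",
            sprintf("gene missing from Ct table: %s", missC[1L]),
            gene = missC[1L])
  if (length(candidateGenes) - removeRepetitions < 3L)
    .qcStop("pool_exhausted",
            sprintf(paste0("pool exhausted: %d candidates minus %d removals ",
                           "is below the 3-gene minimum required by the ",
                           "stability estimator"),
                    length(candidateGenes), removeRepetitions))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    .qcStop("bad_alpha", "alpha must lie strictly between 0 and 1")
  invisible(TRUE)
}

# Dispatch one model's pairwise tests.
.runPairTests <- function(rqSlice, statMethod, sampleOrder, alpha, logRQ) {
  m <- length(unique(rqSlice$sample))
  switch(statMethod,
         pairwise_t_holm = pairwiseTHolm(rqSlice, sampleOrder, logRQ),
         mann_whitney = mannWhitneyPairs(rqSlice, sampleOrder),
         kruskal_dunn = if (m >= 3L)
           kruskalDunn(rqSlice, sampleOrder, alpha)
         else
           mannWhitneyPairs(rqSlice, sampleOrder),
         stop("unknown stat method: ", statMethod))
}

#' Run the full reference-validation workflow
#'
#' Enumerates all models of the sample universe, performs per-model
#' stability estimation with progressive removal of the least stable
#' candidate up to \code{removeRepetitions} levels, assigns each model its
#' reference (optionally the best across levels), computes relative
#' quantification of every target gene, runs the chosen pairwise statistics,
#' derives comparison values, partial coherence scores, per-gene coherence
#' scores, and the run-level average CS.  The computation is fully
#' deterministic given the inputs and configuration.
#'
#' @inheritParams validateRun
#' @param selectBestRemove if \code{TRUE}, each model's reference comes from
#'   the removal level (0..r) with the lowest selected stability; otherwise
#'   from level r exactly.
#' @param statMethod one of \code{"pairwise_t_holm"} (default),
#'   \code{"mann_whitney"}, \code{"kruskal_dunn"}.  With
#'   \code{"kruskal_dunn"}, two-sample models fall back to Mann-Whitney, as
#'   recommended for two unmatched samples.
#' @param logRQ run the t-tests on log2(RQ) instead of raw RQ.
#' @param useAdjustedP base comparison values on Holm-adjusted p-values
#'   (default) or raw p-values (sensitivity analysis).
#' @param calibrator optional sample whose median RQ rescales each model's
#'   RQs (cosmetic; coherence is invariant to it).
#' @return A \linkS4class{CoherenceAnalysis}.
#' @export
runAnalysis <- function(ct, quant, candidateGenes, targetGenes,
                        removeRepetitions = 0L, selectBestRemove = FALSE,
                        alpha = 0.05,
                        statMethod = c("pairwise_t_holm", "mann_whitney",
                                       "kruskal_dunn"),
                        logRQ = FALSE, useAdjustedP = TRUE,
                        calibrator = NULL) {
  statMethod <- match.arg(statMethod)
  removeRepetitions <- as.integer(removeRepetitions)
  validateRun(ct, quant, candidateGenes, targetGenes, removeRepetitions,
              alpha)
  space <- generateModels(sampleLevels(ct))
  universe <- modelUniverse(space)

  # one-off extraction: the per-model loops work on plain matrices
  if (any(replicateCounts(quant) < 2L))
    .qcStop("insufficient_replicates",
            "insufficient replicates: every sample needs >= 2")
  qSmp <- as.character(colData(quant)$sample)
  qCols <- split(seq_along(qSmp), qSmp)
  yAll <- log2(exprMatrix(quant)[candidateGenes, , drop = FALSE])
  cSmp <- as.character(colData(ct)$sample)
  cRep <- as.integer(colData(ct)$replicate)
  cCols <- split(seq_along(cSmp), cSmp)
  cVal <- exprMatrix(ct)

  stabRows <- list()
  assignRows <- list()
  finalRefs <- vector("list", nModels(space))
  for (mid in seq_len(nModels(space))) {
    samples <- modelSamples(space, mid)
    cols <- unlist(qCols[samples], use.names = FALSE)
    group <- qSmp[cols]
    pool <- candidateGenes
    removed <- character()
    perLevel <- vector("list", removeRepetitions + 1L)
    for (lev in 0:removeRepetitions) {
      core <- .stabilityCore(yAll[pool, cols, drop = FALSE], group)
      perLevel[[lev + 1L]] <- .selectCore(core$single, core$pairs, lev)
      stabRows[[length(stabRows) + 1L]] <- data.frame(
        model_id = mid, level = lev,
        pool = paste(pool, collapse = ";"),
        removed = paste(removed, collapse = ";"),
        reference = paste(perLevel[[lev + 1L]]$reference, collapse = "/"),
        stability = perLevel[[lev + 1L]]$stability,
        stringsAsFactors = FALSE)
      if (lev < removeRepetitions) {
        worst <- .worstSingleGene(core$single)
        removed <- c(removed, worst)
        pool <- setdiff(pool, worst)
      }
    }
    chosen <- if (selectBestRemove) selectBestAcrossLevels(perLevel)
              else perLevel[[removeRepetitions + 1L]]
    finalRefs[[mid]] <- chosen
    assignRows[[mid]] <- data.frame(
      model_id = mid,
      model = paste(samples, collapse = ";"),
      reference = paste(chosen$reference, collapse = "/"),
      stability = chosen$stability,
      chosen_level = chosen$level,
      stringsAsFactors = FALSE)
  }

  rqRows <- list()
  testRows <- list()
  for (mid in seq_len(nModels(space))) {
    samples <- modelSamples(space, mid)
    ref <- finalRefs[[mid]]$reference
    cols <- unlist(cCols[samples], use.names = FALSE)
    refCt <- colMeans(cVal[ref, cols, drop = FALSE])
    for (tg in targetGenes) {
      rqv <- 2^(refCt - cVal[tg, cols])
      slice <- data.frame(sample = cSmp[cols], replicate = cRep[cols],
                          rq = unname(rqv), stringsAsFactors = FALSE)
      if (!is.null(calibrator)) {
        if (!calibrator %in% samples && mid == nModels(space))
          .qcStop("unknown_sample",
                  sprintf("calibrator '%s' is not in the universe",
                          calibrator))
        if (calibrator %in% samples)
          slice$rq <- slice$rq /
            median(slice$rq[slice$sample == calibrator])
      }
      rqRows[[length(rqRows) + 1L]] <- cbind(
        data.frame(model_id = mid, target = tg, stringsAsFactors = FALSE),
        slice)
      res <- .runPairTests(slice, statMethod, universe, alpha, logRQ)
      pUsed <- if (useAdjustedP) res$adj_p else res$raw_p
      res$comparison <- vapply(seq_len(nrow(res)), function(j)
        comparisonValue(pUsed[j], res$median1[j], res$median2[j], alpha),
        integer(1L))
      testRows[[length(testRows) + 1L]] <- cbind(
        data.frame(model_id = mid, target = tg, stringsAsFactors = FALSE),
        as.data.frame(res))
    }
  }
  tests <- do.call(rbind, testRows)

  pairsDf <- enumeratePairs(universe)
  partialRows <- list()
  csRows <- list()
  for (tg in targetGenes) {
    partials <- numeric(nrow(pairsDf))
    for (j in seq_len(nrow(pairsDf))) {
      a <- pairsDf$sample1[j]; b <- pairsDf$sample2[j]
      ids <- modelsContainingPair(space, a, b)
      cmp <- tests$comparison[tests$target == tg &
                                tests$sample1 == a & tests$sample2 == b &
                                tests$model_id %in% ids]
      partials[j] <- partialCS(cmp)
      partialRows[[length(partialRows) + 1L]] <- data.frame(
        target = tg, sample1 = a, sample2 = b,
        n_models = length(ids), partial = partials[j],
        stringsAsFactors = FALSE)
    }
    csRows[[length(csRows) + 1L]] <- data.frame(
      target = tg, cs = coherenceScore(partials), stringsAsFactors = FALSE)
  }
  coherence <- do.call(rbind, csRows)

  new("CoherenceAnalysis",
      modelSpace = space,
      stability = do.call(rbind, stabRows),
      assignments = do.call(rbind, assignRows),
      rq = do.call(rbind, rqRows),
      tests = tests,
      partials = do.call(rbind, partialRows),
      coherence = coherence,
      avgCS = averageCS(coherence$cs),
      config = list(candidateGenes = candidateGenes,
                    targetGenes = targetGenes,
                    removeRepetitions = removeRepetitions,
                    selectBestRemove = selectBestRemove,
                    alpha = alpha, statMethod = statMethod,
                    logRQ = logRQ, useAdjustedP = useAdjustedP,
                    calibrator = calibrator))
}
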