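#' Ct value of a reference gene or gene pair
#'
#' A single reference gene contributes its own Ct; a pair contributes the
#' arithmetic mean of the two Cts, which on the linear scale is the
#' geometric mean of the two quantities.
#'
#' @param ct Ct-scale \linkS4class{ExpressionTable}.
#' @param reference character vector of one or two gene names.
#' @param sample,replicate coordinates of the measurement.
#' @return The (averaged) reference Ct.
#' @export
referenceCt <- function(ct, reference, sample, replicate) {
  missing <- setdiff(reference, geneNames(ct))
  if (length(missing))
    .qcStop("unknown_gene", sprintf("gene not in table: %s", missing[1L]),
            gene = missing[1L])
  cd <- colData(ct)
  j <- which(as.character(cd$sample) == sample &
               as.integer(cd$replicate) == as.integer(replicate))
  if (length(j) != 1L)
    .qcStop("unknown_sample",
            sprintf("no measurement for sample '%s', replicate %s",
                    sample, replicate))
  mean(exprMatrix(ct)[reference, j])
}

# Vectorized reference Ct over a set of columns.
.refCtCols <- function(ct, reference, cols) {
  v <- exprMatrix(ct)[reference, cols, drop = FALSE]
  colMeans(v)
}

#' Relative quantification of a target gene within one model
#'
#' Per replicate, \code{RQ = 2^(Ct_ref - Ct_target)} with the model's
#' assigned reference (single gene or averaged pair).  No calibrator
#' rescaling is applied: all downstream comparison values and coherence
#' scores are invariant to a common positive rescaling of a model's RQs.
#' An optional calibrator sample divides all RQs by that sample's median RQ
#' (cosmetic only).
#'
#' @param ct Ct-scale \linkS4class{ExpressionTable}.
#' @param model character vector of model samples.
#' @param target target gene name.
#' @param reference character vector of one or two reference genes (e.g. the
#'   \code{reference} element of \code{\link{selectReference}}).
#' @param calibrator optional sample name used as calibrator.
#' @return data.frame with columns \code{sample}, \code{replicate},
#'   \code{rq} (positive).
#' @export
computeRQ <- function(ct, model, target, reference, calibrator = NULL) {
  stopifnot(is(ct, "ExpressionTable"))
  allGenes <- c(target, reference)
  missing <- setdiff(allGenes, geneNames(ct))
  if (length(missing))
    .qcStop("unknown_gene", sprintf("gene not in table: %s", missing[1L]),
            gene = missing[1L])
  missingS <- setdiff(model, sampleLevels(ct))
  if (length(missingS))
    .qcStop("unknown_sample", sprintf("unknown sample: %s", missingS[1L]))
  cols <- .colsForSamples(ct, model)
  cd <- colData(ct)
  refCt <- .refCtCols(ct, reference, cols)
  tgtCt <- exprMatrix(ct)[target, cols]
  rq <- 2^(refCt - tgtCt)
  out <- data.frame(sample = as.character(cd$sample)[cols],
                    replicate = as.integer(cd$replicate)[cols],
                    rq = unname(rq), stringsAsFactors = FALSE)
  if (!is.null(calibrator)) {
    if (!calibrator %in% model)
      .qcStop("unknown_sample",
              sprintf("calibrator '%s' is not in the model", calibrator))
    out$rq <- out$rq / median(out$rq[out$sample == calibrator])
  }
  out
}
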