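#' ExpressionTable: replicate-level qPCR measurements
#'
#' An \linkS4class{SummarizedExperiment} holding one assay \code{"exprs"}
#' (genes in rows, biological replicates in columns) together with the
#' measurement scale: \code{"ct"} for raw cycle-threshold values or
#' \code{"quantity"} for calibration-curve-derived (strictly positive)
#' expression quantities.  Columns are grouped by sample in first-appearance
#' order; that order is preserved verbatim because the fixed sample order is
#' part of the coherence-score contract downstream.
#'
#' @slot scale character, \code{"ct"} or \code{"quantity"}.
#'
#' @export
setClass("ExpressionTable",
         contains = "SummarizedExperiment",
         slots = c(scale = "character"))

setValidity("ExpressionTable", function(object) {
  msgs <- character()
  if (length(object@scale) != 1L || !object@scale %in% c("ct", "quantity"))
    msgs <- c(msgs, "scale must be one of 'ct', 'quantity'")
  if (!"exprs" %in% assayNames(object))
    msgs <- c(msgs, "assay 'exprs' is required")
  else {
    v <- assay(object, "exprs")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msgs <- c(msgs, "gene (row) names must be present and unique")
    if (anyNA(v) || any(!is.finite(v)))
      msgs <- c(msgs, "all cells must be present and finite")
    else if (identical(object@scale, "quantity") && any(v <= 0))
      msgs <- c(msgs, "quantity-scale values must be strictly positive")
  }
  cd <- colData(object)
  if (!all(c("sample", "replicate") %in% colnames(cd)))
    msgs <- c(msgs, "colData must contain 'sample' and 'replicate'")
  else {
    smp <- as.character(cd$sample)
    rep <- as.integer(cd$replicate)
    # samples must form contiguous blocks, replicates 1..n within each block
    rle_s <- rle(smp)
    if (anyDuplicated(rle_s$values))
      msgs <- c(msgs, "columns of one sample must be contiguous")
    for (s in unique(smp)) {
      r <- rep[smp == s]
      if (!identical(r, seq_along(r)))
        msgs <- c(msgs, sprintf("replicates of sample '%s' must be 1..n", s))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionTable
#'
#' @param values numeric matrix, genes x replicate columns, with unique row
#'   names (gene identifiers).
#' @param sample character vector, one sample identifier per column; columns
#'   of one sample must be contiguous.
#' @param replicate integer vector, replicate index per column (1..n within
#'   each sample).
#' @param scale \code{"ct"} or \code{"quantity"}.
#' @return An \linkS4class{ExpressionTable}.
#' @examples
#' m <- matrix(20 + seq_len(12) / 10, nrow = 2,
#'             dimnames = list(c("G1", "G2"), NULL))
#' ExpressionTable(m, rep(c("A", "B", "C"), each = 2), rep(1:2, 3), "ct")
#' @export
ExpressionTable <- function(values, sample, replicate,
                            scale = c("ct", "quantity")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), ncol(values) == length(sample),
            length(sample) == length(replicate))
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(sample = as.character(sample),
                        replicate = as.integer(replicate)))
  new("ExpressionTable", se, scale = scale)
}

#' @describeIn ExpressionTable measurement scale ("ct" or "quantity").
#' @param x an ExpressionTable.
#' @export
exprScale <- function(x) x@scale

#' @describeIn ExpressionTable sample identifiers in their fixed order.
#' @export
sampleLevels <- function(x) unique(as.character(colData(x)$sample))

#' @describeIn ExpressionTable named integer vector of replicate counts per
#'   sample.
#' @export
replicateCounts <- function(x) {
  smp <- as.character(colData(x)$sample)
  tab <- table(factor(smp, levels = sampleLevels(x)))
  setNames(as.integer(tab), names(tab))
}

#' @describeIn ExpressionTable gene identifiers (row names).
#' @export
geneNames <- function(x) rownames(x)

#' @describeIn ExpressionTable the genes x replicates value matrix.
#' @export
exprMatrix <- function(x) assay(x, "exprs")

# Column indices belonging to the given samples (order: sample blocks in the
# order requested, replicates within).
.colsForSamples <- function(x, samples) {
  smp <- as.character(colData(x)$sample)
  unlist(lapply(samples, function(s) which(smp == s)), use.names = FALSE)
}

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable (%s scale): %d genes x %d replicate columns\n",
              object@scale, nrow(object), ncol(object)))
  cat("samples:", paste(sampleLevels(object), collapse = ", "), "\n")
  cat("replicates per sample:",
      paste(replicateCounts(object), collapse = ", "), "\n")
  cat("genes:", paste(geneNames(object), collapse = ", "), "\n")
})
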