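#' Comparison value of one sample pair in one model
#'
#' Encodes the significant direction of a target gene's expression
#' difference between the pair's first and second sample (fixed universe
#' order): 0 when the (adjusted) p-value is >= \code{alpha}; +1 when
#' significant and the first sample's median RQ is larger; -1 when
#' significant and smaller.  Significant but exactly equal medians map to 0
#' (a documented convention, unreachable with continuous RQ values).
#'
#' @param adjP p-value used for the call (adjusted by default in the
#'   pipeline).
#' @param median1,median2 median RQ of the pair's first/second sample.
#' @param alpha significance level.
#' @return Integer in \{-1, 0, +1\}.
#' @export
comparisonValue <- function(adjP, median1, median2, alpha = 0.05) {
  stopifnot(is.finite(adjP), is.finite(median1), is.finite(median2))
  if (adjP >= alpha || median1 == median2) return(0L)
  if (median1 > median2) 1L else -1L
}

#' Partial coherence score of one sample pair
#'
#' A pair's comparison values across all models containing it are coherent
#' (partial CS = 1) unless both +1 and -1 occur (partial CS = 0): the same
#' two samples must never show significant differences in opposite
#' directions, whatever the model and hence whatever the reference used.
#'
#' @param comparisons integer vector of comparison values in \{-1, 0, +1\}.
#' @return 0 or 1.
#' @export
partialCS <- function(comparisons) {
  if (!length(comparisons))
    .qcStop("empty_comparisons", "no comparison values supplied")
  stopifnot(all(comparisons %in% c(-1L, 0L, 1L)))
  if (any(comparisons == 1L) && any(comparisons == -1L)) 0L else 1L
}

#' Coherence score of one target gene
#'
#' Arithmetic mean of the partial coherence scores over all C(n,2) sample
#' pairs of the universe.
#'
#' @param partials numeric vector with one partial CS (0/1) per universe
#'   pair.
#' @return CS in [0, 1].
#' @export
coherenceScore <- function(partials) {
  if (!length(partials))
    .qcStop("empty_comparisons", "no partial scores supplied")
  stopifnot(all(partials %in% c(0, 1)))
  mean(partials)
}

#' @rdname averageCS
setMethod("averageCS", "numeric", function(x) {
  if (!length(x)) .qcStop("empty_comparisons", "no CS values supplied")
  mean(x)
})
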