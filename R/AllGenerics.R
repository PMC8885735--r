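#' Average coherence score across target genes
#'
#' @param x numeric vector of per-target-gene CS values, or a
#'   \linkS4class{CoherenceAnalysis}.
#' @return Unweighted arithmetic mean CS.
#' @export
setGeneric("averageCS", function(x) standardGeneric("averageCS"))
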