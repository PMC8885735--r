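#' CoherenceAnalysis: complete result bundle of one run
#'
#' Holds everything one invocation of \code{\link{runAnalysis}} produced:
#' the model space, per-level stability/selection records, the final
#' reference assignment per model, RQ values, pairwise test results with
#' comparison values, per-pair partial coherence scores, per-target-gene
#' coherence scores, the run-level average CS, and an echo of the
#' configuration.
#'
#' @slot modelSpace the \linkS4class{ModelSpace} analysed.
#' @slot stability data.frame: one row per (model, level) selection.
#' @slot assignments data.frame: final reference per model.
#' @slot rq data.frame: RQ per (model, target, sample, replicate).
#' @slot tests data.frame: pairwise results per (model, target, pair).
#' @slot partials data.frame: partial CS per (target, pair).
#' @slot coherence data.frame: CS per target gene.
#' @slot avgCS run-level average CS.
#' @slot config list echoing the run configuration.
#'
#' @include ModelSpace-class.R AllGenerics.R
#' @export
setClass("CoherenceAnalysis",
         slots = c(modelSpace = "ModelSpace",
                   stability = "data.frame",
                   assignments = "data.frame",
                   rq = "data.frame",
                   tests = "data.frame",
                   partials = "data.frame",
                   coherence = "data.frame",
                   avgCS = "numeric",
                   config = "list"))

setValidity("CoherenceAnalysis", function(object) {
  msgs <- character()
  if (nrow(object@assignments) != nModels(object@modelSpace))
    msgs <- c(msgs, "exactly one final reference assignment per model")
  n <- length(modelUniverse(object@modelSpace))
  perPair <- 2^(n - 2)
  if (nrow(object@tests)) {
    cnt <- table(paste(object@tests$target, object@tests$sample1,
                       object@tests$sample2, sep = "\t"))
    if (any(cnt != perPair))
      msgs <- c(msgs,
                sprintf("every (target, pair) needs exactly %d comparisons",
                        perPair))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CoherenceAnalysis named per-target-gene coherence scores.
#' @param x a CoherenceAnalysis.
#' @export
coherenceScores <- function(x) setNames(x@coherence$cs, x@coherence$target)

#' @rdname averageCS
setMethod("averageCS", "CoherenceAnalysis", function(x) x@avgCS)

#' @describeIn CoherenceAnalysis final reference assignment per model
#'   (data.frame: model_id, reference, stability, chosen_level).
#' @export
referenceAssignments <- function(x) x@assignments

#' @describeIn CoherenceAnalysis per-(model, level) stability/selection
#'   records.
#' @export
stabilityRecords <- function(x) x@stability

#' @describeIn CoherenceAnalysis RQ values per (model, target, sample,
#'   replicate).
#' @export
rqValues <- function(x) x@rq

#' @describeIn CoherenceAnalysis pairwise test results with comparison
#'   values.
#' @export
pairTests <- function(x) x@tests

#' @describeIn CoherenceAnalysis partial coherence scores per (target,
#'   pair).
#' @export
partialScores <- function(x) x@partials

setMethod("show", "CoherenceAnalysis", function(object) {
  u <- modelUniverse(object@modelSpace)
  cat(sprintf("CoherenceAnalysis: %d samples, %d models, %d target genes\n",
              length(u), nModels(object@modelSpace),
              nrow(object@coherence)))
  cat(sprintf("stat method: %s, alpha = %g, remove level %d%s\n",
              object@config$statMethod, object@config$alpha,
              object@config$removeRepetitions,
              if (isTRUE(object@config$selectBestRemove))
                " (best across levels)" else ""))
  cs <- coherenceScores(object)
  cat("coherence scores:\n")
  print(round(cs, 2L))
  cat(sprintf("average CS: %.2f\n", object@avgCS))
})
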