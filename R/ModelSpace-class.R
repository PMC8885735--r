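#' ModelSpace: the experimental model and all daughter models
#'
#' Given an ordered sample universe of size n, the model space holds every
#' combination (without repetition) of two or more samples: the experimental
#' model (all n samples) plus its daughter models.  Models are numbered
#' deterministically: size-major (all 2-sample models first), lexicographic
#' by sample position within a size, experimental model last.  A pair index
#' records, for every sample pair, which models contain both samples
#' (always 2^(n-2) of them).
#'
#' @slot universe ordered character vector of sample identifiers.
#' @slot models list of character vectors, one per model, in id order.
#' @slot pairIndex named list mapping each ordered pair to the integer ids of
#'   the models containing it.
#'
#' @export
setClass("ModelSpace",
         slots = c(universe = "character",
                   models = "list",
                   pairIndex = "list"))

setValidity("ModelSpace", function(object) {
  n <- length(object@universe)
  msgs <- character()
  if (n < 2L) msgs <- c(msgs, "universe must contain at least 2 samples")
  if (length(object@models) != sum(choose(n, 2:n)))
    msgs <- c(msgs, "model count must be sum_{r=2..n} C(n, r)")
  if (!identical(object@models[[length(object@models)]], object@universe))
    msgs <- c(msgs, "the experimental (full) model must be last")
  if (length(msgs)) msgs else TRUE
})

#' Enumerate the experimental model and all daughter models
#'
#' @param universe ordered character vector of distinct sample identifiers
#'   (n >= 2).  Model counts grow as 2^n; a warning is issued above
#'   \code{maxSamples} samples.
#' @param maxSamples soft cap before warning (default 12, ~4083 models).
#' @return A \linkS4class{ModelSpace}.
#' @examples
#' space <- generateModels(c("A", "B", "C", "D", "E"))
#' nModels(space)                     # 26
#' modelsContainingPair(space, "A", "C")
#' @export
generateModels <- function(universe, maxSamples = 12L) {
  universe <- as.character(universe)
  n <- length(universe)
  if (n < 2L)
    .qcStop("universe_too_small",
            "universe too small: at least 2 samples are required")
  if (anyDuplicated(universe))
    .qcStop("duplicate_sample", "sample identifiers must be unique")
  if (n > maxSamples)
    warning(sprintf("%d samples generate %d models; expect long runtimes",
                    n, sum(choose(n, 2:n))))
  models <- list()
  for (size in 2:n) {
    cmb <- combn(n, size)
    for (j in seq_len(ncol(cmb)))
      models[[length(models) + 1L]] <- universe[cmb[, j]]
  }
  pairIndex <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- universe[i]; b <- universe[j]
      ids <- which(vapply(models,
                          function(m) a %in% m && b %in% m, logical(1L)))
      pairIndex[[.pairKey(a, b)]] <- as.integer(ids)
    }
  }
  new("ModelSpace", universe = universe, models = models,
      pairIndex = pairIndex)
}

#' @describeIn generateModels number of models in the space.
#' @param space a \linkS4class{ModelSpace}.
#' @export
nModels <- function(space) length(space@models)

#' @describeIn generateModels the ordered sample universe.
#' @export
modelUniverse <- function(space) space@universe

#' @describeIn generateModels samples of the model with the given id.
#' @param id integer model id (1-based).
#' @export
modelSamples <- function(space, id) {
  stopifnot(length(id) == 1L, id >= 1L, id <= length(space@models))
  space@models[[id]]
}

#' Models containing a given sample pair
#'
#' @param space a \linkS4class{ModelSpace}.
#' @param a,b two distinct samples of the universe.
#' @return Integer vector of model ids whose sample set contains both;
#'   always of length 2^(n-2).
#' @export
modelsContainingPair <- function(space, a, b) {
  u <- space@universe
  if (!(a %in% u) || !(b %in% u))
    .qcStop("unknown_sample",
            sprintf("unknown sample: %s", setdiff(c(a, b), u)[1L]))
  if (identical(a, b))
    .qcStop("identical_samples", "the two samples must be distinct")
  if (match(a, u) > match(b, u)) { tmp <- a; a <- b; b <- tmp }
  space@pairIndex[[.pairKey(a, b)]]
}

#' Enumerate all sample pairs of a universe in fixed order
#'
#' Pairs are ordered within themselves by universe position (first sample
#' precedes second) and listed lexicographically.  This fixed order is part
#' of the coherence-score contract: comparison signs are always expressed
#' relative to it.
#'
#' @param universe ordered character vector of samples, or a
#'   \linkS4class{ModelSpace}.
#' @return data.frame with columns \code{sample1}, \code{sample2};
#'   C(n,2) rows.
#' @export
enumeratePairs <- function(universe) {
  if (is(universe, "ModelSpace")) universe <- universe@universe
  universe <- as.character(universe)
  if (length(universe) < 2L)
    .qcStop("universe_too_small",
            "universe too small: at least 2 samples are required")
  cmb <- combn(length(universe), 2L)
  data.frame(sample1 = universe[cmb[1L, ]],
             sample2 = universe[cmb[2L, ]],
             stringsAsFactors = FALSE)
}

setMethod("show", "ModelSpace", function(object) {
  n <- length(object@universe)
  sizes <- lengths(object@models)
  cat(sprintf("ModelSpace: %d samples, %d models (experimental model last)\n",
              n, length(object@models)))
  cat("universe:", paste(object@universe, collapse = ", "), "\n")
  cat("models per size:",
      paste(sprintf("%d:%d", sort(unique(sizes)),
                    table(sizes)), collapse = ", "), "\n")
})
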