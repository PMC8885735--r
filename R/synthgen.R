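#' Specification for a synthetic replicate-level qPCR dataset
#'
#' Describes per-gene, per-sample mean Ct values with Gaussian replicate
#' noise: candidate reference genes (whose derived quantities feed the
#' stability estimator) and target genes (whose Ct values feed relative
#' quantification).  A fixed seed makes generation fully reproducible.
#'
#' @param sampleNames ordered sample identifiers.
#' @param nReplicates biological replicates per sample (default 3, the
#'   standard qPCR design).
#' @param candidateMeans numeric matrix, candidate genes x samples, of mean
#'   Ct values (row names = gene names).
#' @param candidateSds per-candidate replicate noise SD in cycles (recycled).
#' @param targetMeans numeric matrix, target genes x samples, of mean Ct.
#' @param targetSds per-target replicate noise SD in cycles (recycled).
#' @param seed integer RNG seed.
#' @return A list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(sampleNames, nReplicates = 3L,
                          candidateMeans, candidateSds,
                          targetMeans, targetSds, seed = 1L) {
  sampleNames <- as.character(sampleNames)
  stopifnot(length(sampleNames) >= 2L, nReplicates >= 2L,
            is.matrix(candidateMeans), is.matrix(targetMeans),
            ncol(candidateMeans) == length(sampleNames),
            ncol(targetMeans) == length(sampleNames),
            !is.null(rownames(candidateMeans)),
            !is.null(rownames(targetMeans)))
  candidateSds <- rep_len(candidateSds, nrow(candidateMeans))
  targetSds <- rep_len(targetSds, nrow(targetMeans))
  if (any(!is.finite(candidateMeans)) || any(!is.finite(targetMeans)))
    .qcStop("bad_spec", "mean Ct values must be finite")
  if (any(candidateSds <= 0) || any(targetSds <= 0))
    .qcStop("bad_spec", "replicate noise SDs must be positive")
  structure(list(sampleNames = sampleNames,
                 nReplicates = as.integer(nReplicates),
                 candidateMeans = candidateMeans,
                 candidateSds = candidateSds,
                 targetMeans = targetMeans,
                 targetSds = targetSds,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic Ct table and matching quantity table
#'
#' Draws \code{Ct(s, r, g) = mean_Ct(s, g) + Normal(0, sd_g)} for every
#' gene, sample and replicate, and derives the candidate genes' quantities
#' as \code{2^(-Ct)}, max-rescaled per gene -- the same perfect-efficiency
#' convention as \code{\link{deriveQuantitiesFromCt}}.
#'
#' @param spec a \code{"SyntheticSpec"} from \code{\link{syntheticSpec}}.
#' @return list with elements \code{ct} (all genes, ct scale) and
#'   \code{quant} (candidate genes, quantity scale).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  S <- length(spec$sampleNames)
  R <- spec$nReplicates
  means <- rbind(spec$candidateMeans, spec$targetMeans)
  sds <- c(spec$candidateSds, spec$targetSds)
  nGenes <- nrow(means)
  cols <- S * R
  ctm <- matrix(NA_real_, nGenes, cols,
                dimnames = list(rownames(means), NULL))
  sampleCol <- rep(spec$sampleNames, each = R)
  repCol <- rep(seq_len(R), S)
  for (i in seq_len(nGenes))
    ctm[i, ] <- means[i, match(sampleCol, spec$sampleNames)] +
      rnorm(cols, 0, sds[i])
  ct <- ExpressionTable(ctm, sampleCol, repCol, "ct")
  quant <- deriveQuantitiesFromCt(ct, efficiency = 2,
                                  genes = rownames(spec$candidateMeans))
  list(ct = ct, quant = quant)
}

#' Coherent scenario: stable references, strictly ordered targets
#'
#' All candidate reference genes have sample-independent mean Ct (no
#' sample-by-gene interaction); target genes have strictly ordered per-sample
#' means separated by \code{effectSize} cycles.  With noise well below the
#' effect size, the full pipeline yields CS = 1 for every target.
#'
#' @param sampleNames ordered sample identifiers (default five cell-line-like
#'   samples).
#' @param nReplicates replicates per sample (default 3).
#' @param nCandidates number of stable candidate reference genes (default 4).
#' @param nTargets number of target genes (default 3).
#' @param effectSize between-adjacent-sample target difference in Ct cycles
#'   (default 2).
#' @param noiseSd replicate noise SD in cycles (default 0.1).
#' @param seed RNG seed.
#' @return list with \code{ct}, \code{quant}, \code{spec},
#'   \code{candidateGenes}, \code{targetGenes}.
#' @export
makeCoherentScenario <- function(sampleNames = paste0("S", 1:5),
                                 nReplicates = 3L, nCandidates = 4L,
                                 nTargets = 3L, effectSize = 2,
                                 noiseSd = 0.1, seed = 1L) {
  S <- length(sampleNames)
  cand <- matrix(rep(18 + seq_len(nCandidates), S), ncol = S,
                 dimnames = list(sprintf("REF%d", seq_len(nCandidates)),
                                 sampleNames))
  tgt <- t(vapply(seq_len(nTargets), function(i)
    23 + i + effectSize * (seq_len(S) - 1L), numeric(S)))
  dimnames(tgt) <- list(sprintf("TGT%d", seq_len(nTargets)), sampleNames)
  spec <- syntheticSpec(sampleNames, nReplicates, cand, noiseSd, tgt,
                        noiseSd, seed)
  c(generateDataset(spec),
    list(spec = spec, candidateGenes = rownames(cand),
         targetGenes = rownames(tgt)))
}

#' Incoherent scenario: one candidate reference with a sample-dependent bias
#'
#' Three well-behaved candidate genes carry moderate replicate noise; a
#' fourth candidate is technically very quiet (tiny replicate noise) but has
#' its mean Ct shifted by \code{biasCycles} in the last
#' \code{nBiasedSamples} samples.  In models mixing shifted and unshifted
#' samples, the quiet-but-biased gene contaminates the selected reference
#' (typically inside the best pair), distorting target RQs by half the bias
#' and flipping the significant direction of moderate true differences --
#' whereas in other models the direction follows the truth.  The result is a
#' contradiction (CS < 1) at removal level 0 for at least one target; one
#' removal round discards the biased gene in the affected models and
#' restores coherence.
#'
#' @param sampleNames ordered sample identifiers (default five).
#' @param nReplicates replicates per sample (default 3).
#' @param biasCycles Ct shift of the biased candidate in the biased samples
#'   (default 3).
#' @param nBiasedSamples number of trailing samples carrying the shift
#'   (default 2).
#' @param targetEffect central true target Ct increase in the biased samples
#'   (default 0.75 cycles, half of \code{biasCycles}/2: the true effect and
#'   the sign-flipped effect under a contaminated pair reference then have
#'   comparable magnitudes and both reach significance).  Three targets are
#'   generated at 0.8x, 1.0x and 1.2x this effect so that the
#'   clean/distorted significance balance is probed at several depths.
#' @param goodSd replicate noise SD of the well-behaved candidates
#'   (default 0.2).
#' @param biasedSd replicate noise SD of the biased candidate
#'   (default 0.1).
#' @param targetSd replicate noise SD of the targets (default 0.08).
#' @param seed RNG seed.
#' @return Same layout as \code{\link{makeCoherentScenario}}, plus
#'   \code{biasedGene}.
#' @export
makeIncoherentScenario <- function(sampleNames = paste0("S", 1:5),
                                   nReplicates = 3L, biasCycles = 3,
                                   nBiasedSamples = 2L, targetEffect = 0.75,
                                   goodSd = 0.2, biasedSd = 0.1,
                                   targetSd = 0.08, seed = 1L) {
  S <- length(sampleNames)
  stopifnot(nBiasedSamples >= 1L, nBiasedSamples < S)
  biased <- seq(S - nBiasedSamples + 1L, S)
  cand <- matrix(rep(c(19, 20, 21, 20), S), ncol = S,
                 dimnames = list(c("REF1", "REF2", "REF3", "UNS1"),
                                 sampleNames))
  cand["UNS1", biased] <- cand["UNS1", biased] + biasCycles
  effects <- targetEffect * c(0.8, 1, 1.2)
  tgt <- matrix(rep(23 + seq_along(effects), S), ncol = S,
                dimnames = list(sprintf("TGT%d", seq_along(effects)),
                                sampleNames))
  for (i in seq_along(effects))
    tgt[i, biased] <- tgt[i, biased] + effects[i]
  spec <- syntheticSpec(sampleNames, nReplicates, cand,
                        c(goodSd, goodSd, goodSd, biasedSd),
                        tgt, targetSd, seed)
  c(generateDataset(spec),
    list(spec = spec, candidateGenes = rownames(cand),
         targetGenes = rownames(tgt), biasedGene = "UNS1"))
}
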