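# Pairwise significance testing of RQ values within one model.
#
# All three methods share a contract: input is a data.frame with columns
# sample, replicate, rq (one model, one target gene); output is one row per
# sample pair (ordered by `sampleOrder`, i.e. the fixed universe order) with
# raw and Holm-adjusted p-values and the two per-sample medians of RQ.  The
# Holm family is exactly the set of pairs within one (model, target) --
# pooling across genes or models would couple unrelated analyses.

.pairsWithin <- function(samples, sampleOrder) {
  samples <- samples[order(match(samples, sampleOrder))]
  if (length(samples) < 2L)
    .qcStop("universe_too_small", "a model needs at least 2 samples")
  cmb <- combn(samples, 2L)
  data.frame(sample1 = cmb[1L, ], sample2 = cmb[2L, ],
             stringsAsFactors = FALSE)
}

.finishPairTests <- function(rq, prs, rawP) {
  med <- vapply(split(rq$rq, rq$sample), median, numeric(1L))
  data.frame(sample1 = prs$sample1, sample2 = prs$sample2,
             raw_p = rawP,
             adj_p = pmin(1, p.adjust(rawP, method = "holm")),
             median1 = unname(med[prs$sample1]),
             median2 = unname(med[prs$sample2]),
             stringsAsFactors = FALSE)
}

#' Pairwise pooled-variance t-tests with Holm adjustment
#'
#' Two-sided two-sample t-tests (classic pooled variance) on RQ values for
#' all sample pairs of one model, Holm step-down adjusted over exactly that
#' family.  When both groups are constant, the p-value is 1 for equal means
#' (no evidence of a difference) and 0 for unequal means (the zero-variance
#' limit).
#'
#' @param rq data.frame with columns \code{sample}, \code{replicate},
#'   \code{rq} for one model and one target gene.
#' @param sampleOrder fixed universe order used to orient the pairs.
#' @param logScale test \code{log2(rq)} instead of raw RQ (medians are
#'   always reported on the raw scale).
#' @return data.frame with columns \code{sample1}, \code{sample2},
#'   \code{raw_p}, \code{adj_p}, \code{median1}, \code{median2}.
#' @export
pairwiseTHolm <- function(rq, sampleOrder = unique(rq$sample),
                          logScale = FALSE) {
  prs <- .pairsWithin(unique(rq$sample), sampleOrder)
  val <- if (logScale) log2(rq$rq) else rq$rq
  rawP <- vapply(seq_len(nrow(prs)), function(j) {
    x <- val[rq$sample == prs$sample1[j]]
    y <- val[rq$sample == prs$sample2[j]]
    if (var(x) == 0 && var(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y, var.equal = TRUE)$p.value
  }, numeric(1L))
  .finishPairTests(rq, prs, rawP)
}

#' Pairwise Mann-Whitney (Wilcoxon rank-sum) tests
#'
#' Exact two-sided p-values when both groups have at most 8 observations and
#' no ties occur; otherwise the normal approximation with tie correction.
#' Recommended for two-sample models; for larger models each pair is tested
#' and Holm-adjusted like the other methods.
#'
#' @inheritParams pairwiseTHolm
#' @return Same layout as \code{\link{pairwiseTHolm}}.
#' @export
mannWhitneyPairs <- function(rq, sampleOrder = unique(rq$sample)) {
  prs <- .pairsWithin(unique(rq$sample), sampleOrder)
  rawP <- vapply(seq_len(nrow(prs)), function(j) {
    x <- rq$rq[rq$sample == prs$sample1[j]]
    y <- rq$rq[rq$sample == prs$sample2[j]]
    if (length(unique(c(x, y))) == 1L) return(1)  # every value tied
    ties <- anyDuplicated(c(x, y)) > 0L
    useExact <- !ties && length(x) <= 8L && length(y) <= 8L
    suppressWarnings(
      wilcox.test(x, y, exact = useExact, correct = TRUE)$p.value)
  }, numeric(1L))
  .finishPairTests(rq, prs, rawP)
}

#' Kruskal-Wallis omnibus with Dunn's post hoc pairwise tests
#'
#' Kruskal-Wallis rank test (tie-corrected) over all model samples; when the
#' omnibus test is significant at \code{alpha}, Dunn's z-tests compare all
#' pairs on the joint ranks (tie-corrected, two-sided, Holm-adjusted).  When
#' the omnibus p-value is >= \code{alpha}, all pairwise adjusted p-values
#' are forced to 1.
#'
#' @inheritParams pairwiseTHolm
#' @param alpha omnibus significance gate (default 0.05).
#' @return Same layout as \code{\link{pairwiseTHolm}}, with attributes
#'   \code{H} (omnibus statistic) and \code{omnibus_p}.
#' @export
kruskalDunn <- function(rq, sampleOrder = unique(rq$sample), alpha = 0.05) {
  samples <- unique(rq$sample)
  if (length(samples) < 3L)
    .qcStop("too_few_groups",
            "Kruskal-Wallis/Dunn needs >= 3 samples; use mannWhitneyPairs")
  prs <- .pairsWithin(samples, sampleOrder)
  g <- factor(rq$sample, levels = samples)
  N <- nrow(rq)
  rk <- rank(rq$rq)
  tieTab <- table(rk)
  tieTerm <- sum(tieTab^3 - tieTab)
  sigma2 <- N * (N + 1) / 12 - tieTerm / (12 * (N - 1))
  if (sigma2 <= 0) {            # every observation tied
    H <- 0; omnibusP <- 1
    rawP <- rep(1, nrow(prs))
  } else {
    kw <- suppressWarnings(kruskal.test(rq$rq, g))
    H <- unname(kw$statistic); omnibusP <- kw$p.value
    rbar <- vapply(split(rk, g), mean, numeric(1L))
    ns <- vapply(split(rk, g), length, integer(1L))
    rawP <- vapply(seq_len(nrow(prs)), function(j) {
      a <- prs$sample1[j]; b <- prs$sample2[j]
      z <- (rbar[a] - rbar[b]) / sqrt(sigma2 * (1 / ns[a] + 1 / ns[b]))
      2 * pnorm(-abs(z))
    }, numeric(1L))
  }
  out <- .finishPairTests(rq, prs, rawP)
  if (!is.na(omnibusP) && omnibusP >= alpha) out$adj_p <- rep(1, nrow(out))
  attr(out, "H") <- H
  attr(out, "omnibus_p") <- omnibusP
  out
}
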