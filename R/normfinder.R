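#' StabilityTable: per-model gene-stability estimates
#'
#' Result of the model-based stability decomposition for one model and one
#' candidate pool: a stability value (rho, lower = more stable) for every
#' single gene and for every unordered gene pair.
#'
#' @slot modelSamples samples of the model the estimates refer to.
#' @slot pool candidate genes used (k >= 3).
#' @slot removed genes removed before this level, in removal order.
#' @slot level removal level the table belongs to (r >= 0).
#' @slot single named numeric vector of single-gene stability values.
#' @slot pairs data.frame with columns gene1, gene2, stability.
#'
#' @export
setClass("StabilityTable",
         slots = c(modelSamples = "character",
                   pool = "character",
                   removed = "character",
                   level = "integer",
                   single = "numeric",
                   pairs = "data.frame"))

setValidity("StabilityTable", function(object) {
  msgs <- character()
  if (length(object@pool) < 3L)
    msgs <- c(msgs, "pool must contain at least 3 genes")
  if (any(!is.finite(object@single)) || any(object@single < 0))
    msgs <- c(msgs, "single-gene stability values must be finite and >= 0")
  if (nrow(object@pairs) &&
      (any(!is.finite(object@pairs$stability)) ||
       any(object@pairs$stability < 0)))
    msgs <- c(msgs, "pair stability values must be finite and >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StabilityTable", function(object) {
  cat(sprintf("StabilityTable: model {%s}, level %d, pool of %d genes\n",
              paste(object@modelSamples, collapse = ", "),
              object@level, length(object@pool)))
  s <- sort(object@single)
  cat("single-gene stability:\n")
  print(round(s, 4L))
  best <- object@pairs[which.min(object@pairs$stability), , drop = FALSE]
  if (nrow(best))
    cat(sprintf("best pair: %s/%s (%.4f)\n",
                best$gene1, best$gene2, best$stability))
})

# Core decomposition on a log2-quantity matrix.
# y: k x m matrix (pool genes x replicate columns), group: sample id/column.
# Returns list(single, pairs, dtilde, v).
.stabilityCore <- function(y, group) {
  k <- nrow(y)
  groups <- unique(group)
  G <- length(groups)
  gidx <- lapply(groups, function(s) which(group == s))
  n_g <- lengths(gidx)

  # (1) subtract the pool-gene mean within each (sample, replicate) column
  z <- sweep(y, 2L, colMeans(y))

  # (2) replicate means and intergroup variation
  zbar <- vapply(gidx, function(cols) rowMeans(z[, cols, drop = FALSE]),
                 numeric(k))                       # k x G
  d <- zbar - rowMeans(zbar)

  # (3) within-sample variances, bias-corrected for the gene-mean subtraction
  s2 <- vapply(gidx, function(cols) {
    zc <- z[, cols, drop = FALSE]
    rowSums((zc - rowMeans(zc))^2) / (length(cols) - 1L)
  }, numeric(k))                                   # k x G
  Shat <- colSums(s2) / (1 - 1 / k)
  sigma2 <- (s2 - rep(Shat / k^2, each = k)) / (1 - 2 / k)
  sigma2[sigma2 < 0] <- 0

  # (4) variance of the intergroup variation
  sig_n <- sweep(sigma2, 2L, n_g, "/")             # sigma^2_ig / n_g
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - sum(sig_n) / (G * k))

  # (5) shrunken intergroup variation; 0/0 handled as 0
  den <- gamma2 + sig_n
  shrink <- ifelse(den > 0, gamma2 / den, 0)
  dtilde <- d * shrink

  # (6) single-gene stability
  v <- sig_n * shrink
  single <- rowMeans(abs(dtilde) + sqrt(v))
  names(single) <- rownames(y)

  # (7) pair stability
  prs <- combn(rownames(y), 2L)
  pstab <- vapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1L, j]; b <- prs[2L, j]
    mean(abs((dtilde[a, ] + dtilde[b, ]) / 2) + sqrt((v[a, ] + v[b, ]) / 4))
  }, numeric(1L))
  pairs <- data.frame(gene1 = prs[1L, ], gene2 = prs[2L, ],
                      stability = pstab, stringsAsFactors = FALSE)
  list(single = single, pairs = pairs)
}

# Shared pre-flight for stability computations.
.stabilityInput <- function(quant, model, pool) {
  stopifnot(is(quant, "ExpressionTable"))
  if (exprScale(quant) != "quantity")
    .qcStop("wrong_scale", "stability estimation needs quantity-scale values")
  if (is(model, "ModelSpace"))
    stop("pass the samples of one model, not a ModelSpace")
  model <- as.character(model)
  if (length(model) < 2L)
    .qcStop("universe_too_small", "a model needs at least 2 samples")
  missingS <- setdiff(model, sampleLevels(quant))
  if (length(missingS))
    .qcStop("unknown_sample", sprintf("unknown sample: %s", missingS[1L]))
  missingG <- setdiff(pool, geneNames(quant))
  if (length(missingG))
    .qcStop("unknown_gene", sprintf("gene not in table: %s", missingG[1L]),
            gene = missingG[1L])
  if (length(pool) < 3L)
    .qcStop("pool_exhausted",
            "pool exhausted: at least 3 candidate genes are required")
  nrep <- replicateCounts(quant)[model]
  if (any(nrep < 2L))
    .qcStop("insufficient_replicates",
            sprintf("insufficient replicates for sample '%s' (need >= 2)",
                    model[which(nrep < 2L)[1L]]))
  cols <- .colsForSamples(quant, model)
  list(y = log2(exprMatrix(quant)[pool, cols, drop = FALSE]),
       group = as.character(colData(quant)$sample)[cols],
       model = model)
}

#' Model-based stability estimation for a candidate gene pool
#'
#' Implements the NormFinder-type variance decomposition on log2-transformed
#' quantities within one model: per-column gene-mean subtraction, separation
#' of inter-sample variation (shrunken towards zero) and intra-sample
#' variance (bias-corrected for the mean subtraction, negative estimates
#' clamped to zero), and a combined stability value per single gene and per
#' unordered gene pair.  Lower values indicate more stable expression.
#'
#' Samples play the role of groups; biological replicates are the
#' within-group observations.  The per-column mean subtraction makes the
#' result exactly invariant to rescaling all quantities of one replicate by
#' a positive constant.
#'
#' @param quant quantity-scale \linkS4class{ExpressionTable} containing at
#'   least the pool genes.
#' @param model character vector of model samples (>= 2, each with >= 2
#'   replicates).
#' @param pool candidate reference genes (>= 3).
#' @param level removal level this pool corresponds to (bookkeeping only).
#' @param removed genes removed before this level (bookkeeping only).
#' @return A \linkS4class{StabilityTable}.
#' @export
stabilityForPool <- function(quant, model, pool, level = 0L,
                             removed = character()) {
  inp <- .stabilityInput(quant, model, pool)
  core <- .stabilityCore(inp$y, inp$group)
  new("StabilityTable", modelSamples = inp$model, pool = as.character(pool),
      removed = as.character(removed), level = as.integer(level),
      single = core$single, pairs = core$pairs)
}

#' Select the most stable reference from a stability table
#'
#' Returns the single gene or gene pair with the minimal stability value.
#' Ties between a single gene and a pair go to the single gene; remaining
#' ties are broken lexicographically by gene name(s).
#'
#' @param stab a \linkS4class{StabilityTable}.
#' @return A list with elements \code{reference} (character vector of one or
#'   two genes), \code{stability}, \code{level}, and \code{modelSamples}.
#' @export
selectReference <- function(stab) {
  stopifnot(is(stab, "StabilityTable"))
  sel <- .selectCore(stab@single, stab@pairs, stab@level)
  sel$modelSamples <- stab@modelSamples
  sel
}

# Selection on plain structures (shared with the pipeline fast path).
.selectCore <- function(single, pairs, level) {
  pairLabel <- paste(pmin(pairs$gene1, pairs$gene2),
                     pmax(pairs$gene1, pairs$gene2), sep = "/")
  label <- c(names(single), pairLabel)
  stability <- c(unname(single), pairs$stability)
  isSingle <- c(rep(TRUE, length(single)), rep(FALSE, nrow(pairs)))
  # order: stability, then single-before-pair, then label; first row wins
  best <- order(stability, !isSingle, label)[1L]
  list(reference = strsplit(label[best], "/", fixed = TRUE)[[1L]],
       stability = stability[best],
       level = as.integer(level))
}

#' Iteratively remove the least stable candidate gene within one model
#'
#' At each of \code{r} iterations, single-gene stability values are
#' recomputed on the current pool and the gene with the largest value is
#' removed (ties: lexicographically last).  Removal is per model: different
#' models may discard different genes.
#'
#' @inheritParams stabilityForPool
#' @param r number of removal iterations; \code{length(pool) - r >= 3}.
#' @return list with \code{pool} (reduced) and \code{removed}
#'   (genes in removal order).
#' @export
removeLeastStable <- function(quant, model, pool, r) {
  r <- as.integer(r)
  stopifnot(r >= 0L)
  if (length(pool) - r < 3L)
    .qcStop("pool_exhausted",
            sprintf(paste0("pool exhausted: removing %d of %d genes leaves ",
                           "fewer than the 3-gene minimum"),
                    r, length(pool)))
  removed <- character()
  for (i in seq_len(r)) {
    stab <- stabilityForPool(quant, model, pool)
    worst <- .worstSingleGene(stab@single)
    removed <- c(removed, worst)
    pool <- setdiff(pool, worst)
  }
  list(pool = pool, removed = removed)
}

# Worst gene = largest rho; ties broken lexicographically last.
.worstSingleGene <- function(single) {
  ord <- order(-single, names(single), decreasing = FALSE)
  # order(-rho, name): largest rho first; among equals, names ascending --
  # we want the lexicographically LAST of the tied names.
  top <- names(single)[single == max(single)]
  sort(top)[length(top)]
}

#' Choose the best reference across removal levels of one model
#'
#' With the cross-level option enabled, each model's reference comes from
#' the removal level whose selected reference has the lowest stability
#' value; ties go to the lowest level (fewest genes removed).
#'
#' @param assignments list of reference assignments (as returned by
#'   \code{\link{selectReference}}) for levels 0..r of one model.
#' @return The winning assignment.
#' @export
selectBestAcrossLevels <- function(assignments) {
  if (!length(assignments))
    .qcStop("empty_assignments", "no assignments supplied")
  stab <- vapply(assignments, function(a) a$stability, numeric(1L))
  lev <- vapply(assignments, function(a) a$level, integer(1L))
  assignments[[order(stab, lev)[1L]]]
}
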