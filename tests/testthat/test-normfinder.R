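test_that("stability values match frozen oracle values on the tiny fixture", {
  q <- tinyQuantFixture()
  stab <- stabilityForPool(q, c("S1", "S2"), c("GA", "GB", "GC"))
  expect_equal(stab@single,
               c(GA = 0.1480886696, GB = 0.2323586944, GC = 0.2133138291),
               tolerance = 1e-9)
  expect_equal(stab@pairs$stability,
               c(0.1069906409, 0.1543658168, 0.1430343738),
               tolerance = 1e-9)
})

test_that("vectorized estimator agrees with the loop oracle on random fixtures", {
  cases <- expand.grid(k = 3:5, G = 2:3, rep = 1:4)
  expect_gte(nrow(cases), 20)
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; G <- cases$G[i]
    q <- randomQuantTable(k, G, 3, seed = 1000 + i)
    pool <- geneNames(q)
    stab <- stabilityForPool(q, sampleLevels(q), pool)
    o <- oracleStability(log2(exprMatrix(q)),
                         rep(sampleLevels(q), each = 3))
    expect_equal(stab@single, o$single, tolerance = 1e-6)
    expect_equal(stab@pairs$stability, o$pairs$stability, tolerance = 1e-6)
  }
})

test_that("identical expression everywhere gives zero stability values", {
  m <- matrix(0.5, nrow = 3, ncol = 6,
              dimnames = list(c("A", "B", "C"), NULL))
  q <- ExpressionTable(m, rep(c("S1", "S2"), each = 3), rep(1:3, 2),
                       "quantity")
  stab <- stabilityForPool(q, c("S1", "S2"), c("A", "B", "C"))
  expect_true(all(stab@single == 0))
  expect_true(all(stab@pairs$stability == 0))
})

test_that("stability is invariant to per-replicate scaling and pool order", {
  q <- randomQuantTable(4, 3, 3, seed = 7)
  pool <- geneNames(q)
  base <- stabilityForPool(q, sampleLevels(q), pool)
  v <- exprMatrix(q)
  v[, 2] <- v[, 2] * 17.3            # rescale one replicate column
  v[, 7] <- v[, 7] * 1e-3
  q2 <- ExpressionTable(v, as.character(colData(q)$sample),
                        colData(q)$replicate, "quantity")
  scaled <- stabilityForPool(q2, sampleLevels(q), pool)
  expect_equal(scaled@single, base@single, tolerance = 1e-12)
  expect_equal(scaled@pairs$stability, base@pairs$stability,
               tolerance = 1e-12)
  # permuting the pool permutes but does not change the values
  perm <- stabilityForPool(q, sampleLevels(q), rev(pool))
  expect_equal(perm@single[pool], base@single[pool], tolerance = 1e-12)
})

test_that("reference selection breaks ties single-first then by name", {
  mk <- function(single, pairs) {
    new("StabilityTable", modelSamples = c("S1", "S2"),
        pool = c("A", "B", "C"), removed = character(), level = 0L,
        single = single, pairs = pairs)
  }
  prs <- data.frame(gene1 = "B", gene2 = "C", stability = 0.2,
                    stringsAsFactors = FALSE)
  sel <- selectReference(mk(c(A = 0.2, B = 0.9, C = 0.9), prs))
  expect_identical(sel$reference, "A")          # single preferred on tie
  prs2 <- data.frame(gene1 = c("B", "A"), gene2 = c("C", "C"),
                     stability = c(0.1, 0.1), stringsAsFactors = FALSE)
  sel2 <- selectReference(mk(c(A = 0.5, B = 0.5, C = 0.5), prs2))
  expect_identical(sel2$reference, c("A", "C")) # lexicographic pair tie
  prs3 <- data.frame(gene1 = "B", gene2 = "C", stability = 0.9,
                     stringsAsFactors = FALSE)
  sel3 <- selectReference(mk(c(B = 0.3, A = 0.3, C = 0.5), prs3))
  expect_identical(sel3$reference, "A")         # lexicographic single tie
})

test_that("removal discards the worst gene per model and respects the pool floor", {
  ds <- makeIncoherentScenario(seed = 11)
  u <- sampleLevels(ds$quant)
  r0 <- removeLeastStable(ds$quant, u, ds$candidateGenes, 0)
  expect_identical(r0$pool, ds$candidateGenes)
  expect_identical(r0$removed, character())
  expect_error(removeLeastStable(ds$quant, u, ds$candidateGenes, 2),
               class = "qpcr_pool_exhausted")
  # the deliberately biased gene is removed first in >= 19/20 seeded runs
  hits <- 0L
  for (s in 1:20) {
    ds <- makeIncoherentScenario(seed = s)
    r1 <- removeLeastStable(ds$quant, u, ds$candidateGenes, 1)
    if (identical(r1$removed, ds$biasedGene)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("cross-level selection takes the minimum, ties to the lowest level", {
  mk <- function(stab, lev) list(reference = "X", stability = stab,
                                 level = as.integer(lev))
  picks <- selectBestAcrossLevels(list(mk(0.091, 0), mk(0.171, 1),
                                       mk(0.010, 2)))
  expect_identical(picks$level, 2L)
  expect_equal(picks$stability, 0.010)
  expect_identical(selectBestAcrossLevels(list(mk(0.4, 0)))$level, 0L)
  expect_identical(selectBestAcrossLevels(list(mk(0.2, 0),
                                               mk(0.2, 1)))$level, 0L)
  expect_error(selectBestAcrossLevels(list()),
               class = "qpcr_empty_assignments")
})

test_that("with best-across-levels the chosen stability is non-increasing in r", {
  ds <- makeIncoherentScenario(seed = 5)
  set.seed(1)
  # 5 candidates so removal budget 2 is legal
  q5 <- rbind(exprMatrix(ds$quant),
              REF9 = exprMatrix(ds$quant)["REF1", ] *
                2^rnorm(15, 0, 0.05))
  quant <- ExpressionTable(q5, as.character(colData(ds$quant)$sample),
                           colData(ds$quant)$replicate, "quantity")
  ct5 <- rbind(exprMatrix(ds$ct), REF9 = -log2(q5["REF9", ]))
  ct <- ExpressionTable(ct5, as.character(colData(ds$ct)$sample),
                        colData(ds$ct)$replicate, "ct")
  cand <- c(ds$candidateGenes, "REF9")
  prev <- NULL
  for (r in 0:2) {
    res <- runAnalysis(ct, quant, cand, ds$targetGenes,
                       removeRepetitions = r, selectBestRemove = TRUE)
    st <- referenceAssignments(res)$stability
    if (!is.null(prev)) expect_true(all(st <= prev + 1e-12))
    prev <- st
  }
})

test_that("insufficient replicates and exhausted pools are rejected", {
  q <- randomQuantTable(3, 2, 3, seed = 3)
  expect_error(stabilityForPool(q, sampleLevels(q), geneNames(q)[1:2]),
               class = "qpcr_pool_exhausted")
  one <- ExpressionTable(exprMatrix(q)[, c(1, 4), drop = FALSE],
                         c("S1", "S2"), c(1L, 1L), "quantity")
  expect_error(stabilityForPool(one, c("S1", "S2"), geneNames(q)),
               class = "qpcr_insufficient_replicates")
})
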