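test_that("a well-formed CSV is read completely with file sample order", {
  rows <- fixtureRows(c("B", "A"), 3, c("G1", "G2", "G3", "G4"))
  tab <- readExpressionTable(writeFixtureCsv(rows), "ct")
  expect_s4_class(tab, "ExpressionTable")
  expect_identical(sampleLevels(tab), c("B", "A"))  # file order, not sorted
  expect_identical(dim(exprMatrix(tab)), c(4L, 6L))
  expect_identical(unname(replicateCounts(tab)), c(3L, 3L))
  expect_equal(unname(exprMatrix(tab)["G2", 1]), rows$G2[1])
})

test_that("the five-sample melanoma-style layout yields 165 Ct cells", {
  genes <- c(sprintf("HKG%d", 1:4), sprintf("TG%d", 1:7))
  rows <- fixtureRows(sprintf("line%d", 1:5), 3, genes)
  tab <- readExpressionTable(writeFixtureCsv(rows), "ct")
  expect_identical(length(exprMatrix(tab)), 165L)
  expect_identical(geneNames(tab), genes)
})

test_that("validation rejects incomplete, duplicated and non-positive input", {
  rows <- fixtureRows(c("A", "B"), 3, c("G1", "G2"))
  holed <- rows; holed$G2[4] <- NA
  expect_error(readExpressionTable(writeFixtureCsv(holed), "ct"),
               class = "qpcr_incomplete_table")
  expect_error(readExpressionTable(writeFixtureCsv(holed), "ct"),
               regexp = "sample 'B'.*replicate '1'.*gene 'G2'")
  dup <- rbind(rows, rows[1, ])
  expect_error(readExpressionTable(writeFixtureCsv(dup), "ct"),
               class = "qpcr_duplicate_replicate")
  neg <- rows; neg$G1[2] <- -0.5
  expect_error(readExpressionTable(writeFixtureCsv(neg), "quantity"),
               class = "qpcr_non_positive_quantity")
  expect_silent(readExpressionTable(writeFixtureCsv(neg), "ct"))  # ct may be any finite value
})

test_that("write/read round trip is bit-for-bit and keeps sample order", {
  set.seed(42)
  m <- matrix(rexp(24) + 1e-8, nrow = 4,
              dimnames = list(sprintf("g%d", 1:4), NULL))
  tab <- ExpressionTable(m, rep(c("Z", "M", "A"), each = 2), rep(1:2, 3),
                         "quantity")
  p <- tempfile(fileext = ".csv")
  writeExpressionTable(tab, p)
  back <- readExpressionTable(p, "quantity")
  expect_identical(sampleLevels(back), c("Z", "M", "A"))
  expect_identical(exprMatrix(back), exprMatrix(tab))
})

test_that("quantity derivation from Ct follows the efficiency model", {
  m <- matrix(c(20, 21), nrow = 1, dimnames = list("G1", NULL))
  ct <- ExpressionTable(m, c("A", "A"), 1:2, "ct")
  expect_equal(unname(exprMatrix(deriveQuantitiesFromCt(ct))[1, ]),
               c(1, 0.5))
  # constant Ct -> all quantities 1
  mc <- matrix(rep(23.7, 4), nrow = 1, dimnames = list("G1", NULL))
  ctc <- ExpressionTable(mc, rep(c("A", "B"), each = 2), rep(1:2, 2), "ct")
  expect_true(all(exprMatrix(deriveQuantitiesFromCt(ctc)) == 1))
  # hand-computed: 2^-(23.3219 - 20) = 0.10000069
  m2 <- matrix(c(20, 23.3219), nrow = 1, dimnames = list("G1", NULL))
  ct2 <- ExpressionTable(m2, c("A", "A"), 1:2, "ct")
  expect_equal(unname(exprMatrix(deriveQuantitiesFromCt(ct2))[1, 2]),
               2^(-3.3219), tolerance = 1e-12)
  expect_error(deriveQuantitiesFromCt(ct, efficiency = 2.5),
               class = "qpcr_bad_efficiency")
  expect_error(deriveQuantitiesFromCt(ct, efficiency = 1),
               class = "qpcr_bad_efficiency")
})

test_that("per-gene Ct shifts cancel exactly in derived quantities", {
  rows <- fixtureRows(c("A", "B"), 3, c("G1", "G2"))
  tab <- readExpressionTable(writeFixtureCsv(rows), "ct")
  shifted <- exprMatrix(tab) + c(3.7, -1.2)  # per-gene constants
  tab2 <- ExpressionTable(shifted, as.character(colData(tab)$sample),
                          colData(tab)$replicate, "ct")
  expect_equal(exprMatrix(deriveQuantitiesFromCt(tab)),
               exprMatrix(deriveQuantitiesFromCt(tab2)), tolerance = 1e-12)
})

test_that("run validation enforces pool size, gene sets and sample matching", {
  ds <- makeCoherentScenario(seed = 1)
  expect_true(validateRun(ds$ct, ds$quant, ds$candidateGenes,
                          ds$targetGenes, removeRepetitions = 1))
  expect_error(validateRun(ds$ct, ds$quant, ds$candidateGenes,
                           ds$targetGenes, removeRepetitions = 2),
               class = "qpcr_pool_exhausted")
  expect_error(validateRun(ds$ct, ds$quant, ds$candidateGenes,
                           ds$targetGenes, removeRepetitions = 2),
               regexp = "3-gene minimum")
  # quantity table missing a candidate gene column
  qless <- ExpressionTable(
    exprMatrix(ds$quant)[-1, , drop = FALSE],
    as.character(colData(ds$quant)$sample),
    colData(ds$quant)$replicate, "quantity")
  err <- tryCatch(validateRun(ds$ct, qless, ds$candidateGenes,
                              ds$targetGenes),
                  qpcr_unknown_gene = identity)
  expect_match(conditionMessage(err), ds$candidateGenes[1])
  # sample mismatch between the two tables
  qswap <- ExpressionTable(
    exprMatrix(ds$quant),
    sub("^S1$", "X1", as.character(colData(ds$quant)$sample)),
    colData(ds$quant)$replicate, "quantity")
  expect_error(validateRun(ds$ct, qswap, ds$candidateGenes, ds$targetGenes),
               class = "qpcr_sample_set_mismatch")
  expect_error(validateRun(ds$ct, ds$quant, ds$candidateGenes,
                           ds$targetGenes, alpha = 1),
               class = "qpcr_bad_alpha")
  expect_error(validateRun(ds$ct, ds$quant,
                           c(ds$candidateGenes, ds$targetGenes[1]),
                           ds$targetGenes),
               class = "qpcr_gene_overlap")
})
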