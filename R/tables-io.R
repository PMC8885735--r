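#' Read a replicate-level expression table from CSV
#'
#' The expected layout is one row per biological replicate with the header
#' \code{sample,replicate,<gene1>,<gene2>,...}.  Sample order is the order of
#' first appearance in the file and is preserved verbatim; replicate indices
#' are renumbered contiguously from 1 within each sample (file order).
#' Incomplete tables are rejected, never imputed: the downstream stability
#' decomposition assumes balanced, complete data.
#'
#' @param path path to a CSV file (RFC 4180, UTF-8, dot decimal separator).
#' @param scale \code{"ct"} for raw cycle-threshold values (must be finite)
#'   or \code{"quantity"} for calibration-derived values (must be > 0).
#' @return An \linkS4class{ExpressionTable}.
#' @export
readExpressionTable <- function(path, scale = c("ct", "quantity")) {
  scale <- match.arg(scale)
  if (!file.exists(path))
    .qcStop("file_not_found", sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L ||
      tolower(names(df)[1L]) != "sample" ||
      tolower(names(df)[2L]) != "replicate")
    .qcStop("bad_header",
            "header must be 'sample,replicate,<gene1>,<gene2>,...'")
  genes <- names(df)[-(1:2)]
  if (anyDuplicated(genes))
    .qcStop("duplicate_gene", sprintf("duplicate gene column: %s",
                                      genes[duplicated(genes)][1L]))
  smp <- as.character(df[[1L]])
  repLab <- as.character(df[[2L]])
  dup <- duplicated(paste(smp, repLab, sep = "\t"))
  if (any(dup)) {
    i <- which(dup)[1L]
    .qcStop("duplicate_replicate",
            sprintf("duplicate replicate row: sample '%s', replicate '%s'",
                    smp[i], repLab[i]),
            sample = smp[i], replicate = repLab[i])
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    .qcStop("incomplete_table",
            sprintf(paste0("incomplete table: missing or non-numeric value ",
                           "for sample '%s', replicate '%s', gene '%s'"),
                    smp[i], repLab[i], genes[j]),
            sample = smp[i], replicate = repLab[i], gene = genes[j])
  }
  if (scale == "quantity" && any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    .qcStop("non_positive_quantity",
            sprintf(paste0("non-positive quantity for sample '%s', ",
                           "replicate '%s', gene '%s'"),
                    smp[i], repLab[i], genes[j]),
            sample = smp[i], replicate = repLab[i], gene = genes[j])
  }
  sampleOrder <- unique(smp)
  rowOrder <- order(match(smp, sampleOrder))  # stable: keeps file order within
  vals <- vals[rowOrder, , drop = FALSE]
  smp <- smp[rowOrder]
  repIdx <- unlist(lapply(unique(smp), function(s) seq_len(sum(smp == s))),
                   use.names = FALSE)
  ExpressionTable(t(vals), smp, repIdx, scale)
}

#' Write an ExpressionTable to CSV
#'
#' Inverse of \code{\link{readExpressionTable}}: numbers are written with 17
#' significant digits so that a write/read round trip reproduces values
#' bit-for-bit and preserves sample order.
#'
#' @param x an \linkS4class{ExpressionTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(x, path) {
  cd <- colData(x)
  v <- t(exprMatrix(x))
  df <- data.frame(sample = as.character(cd$sample),
                   replicate = as.integer(cd$replicate),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (g in geneNames(x)) df[[g]] <- sprintf("%.17g", v[, g])
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert Ct values to expression quantities (calibration-free fallback)
#'
#' When no calibration curve is available, quantities can be approximated
#' from Ct values assuming a single amplification efficiency:
#' \code{quantity = efficiency^(-Ct)}, rescaled per gene so that the maximum
#' quantity of each gene equals 1.  This is an opt-in fallback; an analysis
#' mirroring a real calibration-curve design should supply measured
#' quantities instead.  The per-gene rescaling makes the result exactly
#' invariant to adding a per-gene constant to all Ct values.
#'
#' @param ct an \linkS4class{ExpressionTable} on the \code{"ct"} scale.
#' @param efficiency amplification efficiency per cycle, in (1, 2];
#'   2 = perfect doubling (default).
#' @param genes genes to convert (default: all genes in \code{ct}).
#' @return An \linkS4class{ExpressionTable} on the \code{"quantity"} scale.
#' @examples
#' m <- matrix(c(20, 21), nrow = 1, dimnames = list("G1", NULL))
#' ct <- ExpressionTable(m, c("A", "A"), 1:2, "ct")
#' exprMatrix(deriveQuantitiesFromCt(ct))  # 1.0 and 0.5
#' @export
deriveQuantitiesFromCt <- function(ct, efficiency = 2, genes = geneNames(ct)) {
  stopifnot(is(ct, "ExpressionTable"))
  if (exprScale(ct) != "ct")
    .qcStop("wrong_scale", "input table must be on the ct scale")
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 1 || efficiency > 2)
    .qcStop("bad_efficiency", "efficiency must be in (1, 2]")
  missing <- setdiff(genes, geneNames(ct))
  if (length(missing))
    .qcStop("unknown_gene", sprintf("gene not in table: %s", missing[1L]),
            gene = missing[1L])
  v <- exprMatrix(ct)[genes, , drop = FALSE]
  q <- efficiency^(-v)
  q <- q / apply(q, 1L, max)
  cd <- colData(ct)
  ExpressionTable(q, as.character(cd$sample), as.integer(cd$replicate),
                  "quantity")
}
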