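# Write a wide CSV (sample,replicate,genes...) from a matrix of rows =
# replicate records; `rows` is a data.frame already in file layout.
writeFixtureCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# Small deterministic Ct fixture: S samples x R replicates x genes, values
# mean[gene] + 0.1 * replicate so every cell is distinct and predictable.
fixtureRows <- function(samples, reps, genes, base = 20) {
  rows <- expand.grid(replicate = seq_len(reps), sample = samples,
                      stringsAsFactors = FALSE)[, c("sample", "replicate")]
  rows <- rows[order(match(rows$sample, samples), rows$replicate), ]
  for (gi in seq_along(genes))
    rows[[genes[gi]]] <- base + gi +
      0.1 * rows$replicate + 0.01 * match(rows$sample, samples)
  rownames(rows) <- NULL
  rows
}

# A 3-gene / 2-sample / 3-replicate quantity fixture with hand-picked Ct
# values; used with frozen oracle-derived stability values.
tinyQuantFixture <- function() {
  ctm <- matrix(c(20.0, 20.3, 20.1,  21.0, 21.2, 20.9,   # GA
                  18.0, 18.1, 17.9,  18.2, 18.4, 18.3,   # GB
                  22.0, 22.5, 21.8,  23.1, 22.7, 23.4),  # GC
                nrow = 3, byrow = TRUE,
                dimnames = list(c("GA", "GB", "GC"), NULL))
  q <- 2^(-ctm)
  q <- q / apply(q, 1, max)
  ExpressionTable(q, rep(c("S1", "S2"), each = 3), rep(1:3, 2), "quantity")
}
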