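# Independent, deliberately naive (loop-based) walk of the published
# model-based stability formulas.  Kept free of any package internals so it
# can serve as an oracle for the vectorized implementation.
#
# y: k x m matrix of log2 quantities (rows = genes), group: sample id per
# column.  Returns list(single = named numeric, pairs = data.frame).
oracleStability <- function(y, group) {
  k <- nrow(y)
  gl <- unique(group)
  G <- length(gl)

  z <- y
  for (j in seq_len(ncol(y))) z[, j] <- y[, j] - mean(y[, j])

  zbar <- matrix(0, k, G)
  s2 <- matrix(0, k, G)
  n <- integer(G)
  for (gi in seq_len(G)) {
    cols <- which(group == gl[gi])
    n[gi] <- length(cols)
    for (i in seq_len(k)) {
      zbar[i, gi] <- mean(z[i, cols])
      s2[i, gi] <- sum((z[i, cols] - zbar[i, gi])^2) / (n[gi] - 1)
    }
  }
  d <- zbar
  for (i in seq_len(k)) d[i, ] <- zbar[i, ] - mean(zbar[i, ])

  sigma2 <- matrix(0, k, G)
  for (gi in seq_len(G)) {
    Sg <- sum(s2[, gi]) / (1 - 1 / k)
    for (i in seq_len(k))
      sigma2[i, gi] <- max(0, (s2[i, gi] - Sg / k^2) / (1 - 2 / k))
  }

  sumdn <- 0
  for (i in seq_len(k)) for (gi in seq_len(G))
    sumdn <- sumdn + sigma2[i, gi] / n[gi]
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - sumdn / (G * k))

  dt <- matrix(0, k, G)
  v <- matrix(0, k, G)
  for (i in seq_len(k)) for (gi in seq_len(G)) {
    den <- gamma2 + sigma2[i, gi] / n[gi]
    if (den > 0) {
      dt[i, gi] <- d[i, gi] * gamma2 / den
      v[i, gi] <- (sigma2[i, gi] / n[gi]) * gamma2 / den
    }
  }

  single <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(G)) acc <- acc + abs(dt[i, gi]) + sqrt(v[i, gi])
    single[i] <- acc / G
  }
  names(single) <- rownames(y)

  g1 <- character(); g2 <- character(); rho <- numeric()
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    acc <- 0
    for (gi in seq_len(G))
      acc <- acc + abs((dt[a, gi] + dt[b, gi]) / 2) +
        sqrt((v[a, gi] + v[b, gi]) / 4)
    g1 <- c(g1, rownames(y)[a]); g2 <- c(g2, rownames(y)[b])
    rho <- c(rho, acc / G)
  }
  list(single = single,
       pairs = data.frame(gene1 = g1, gene2 = g2, stability = rho,
                          stringsAsFactors = FALSE))
}

# Random quantity-scale fixture: k genes x (G samples x n replicates).
randomQuantTable <- function(k, G, n, seed) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(k))
  samples <- sprintf("S%d", seq_len(G))
  means <- matrix(runif(k * G, 18, 24), k, G)
  ctm <- matrix(0, k, G * n, dimnames = list(genes, NULL))
  for (i in seq_len(k))
    ctm[i, ] <- rep(means[i, ], each = n) + rnorm(G * n, 0, runif(1, .05, .6))
  q <- 2^(-ctm)
  q <- q / apply(q, 1, max)
  ExpressionTable(q, rep(samples, each = n), rep(seq_len(n), G), "quantity")
}
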