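rqFrame <- function(...) {
  groups <- list(...)
  data.frame(sample = rep(names(groups), lengths(groups)),
             replicate = unlist(lapply(groups, seq_along)),
             rq = unlist(groups), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Hand implementation of the Holm step-down definition, used as oracle.
holmByHand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

test_that("Holm adjustment matches the step-down definition by hand", {
  expect_equal(holmByHand(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(9)
  rq <- rqFrame(A = rnorm(3, 1, .2), B = rnorm(3, 1.6, .2),
                C = rnorm(3, 1.3, .2))
  res <- pairwiseTHolm(rq, c("A", "B", "C"))
  expect_equal(res$adj_p, holmByHand(res$raw_p))
  expect_true(all(res$adj_p >= res$raw_p))
  expect_true(all(diff(res$adj_p[order(res$raw_p)]) >= 0))  # monotone
})

test_that("t-tests handle degenerate groups and families of size one", {
  same <- rqFrame(A = c(1, 1, 1), B = c(1, 1, 1))
  expect_equal(pairwiseTHolm(same)$adj_p, 1)
  diffc <- rqFrame(A = c(1, 1, 1), B = c(2, 2, 2))
  expect_equal(pairwiseTHolm(diffc)$adj_p, 0)
  set.seed(1)
  two <- rqFrame(A = rnorm(3, 1), B = rnorm(3, 2))
  res <- pairwiseTHolm(two)
  expect_equal(res$adj_p, res$raw_p)            # single pair family
  # symmetric in group order (medians swap, p identical)
  rev <- rqFrame(B = two$rq[two$sample == "B"],
                 A = two$rq[two$sample == "A"])
  res2 <- pairwiseTHolm(rev, c("A", "B"))
  expect_equal(res2$raw_p, res$raw_p)
  expect_equal(res2$median1, res$median1)
})

test_that("pooled t-test matches stats::t.test on a normal fixture", {
  set.seed(2)
  rq <- rqFrame(A = rnorm(3, 1, .3), B = rnorm(3, 2, .3))
  res <- pairwiseTHolm(rq)
  ref <- t.test(rq$rq[1:3], rq$rq[4:6], var.equal = TRUE)$p.value
  expect_equal(res$raw_p, ref)
})

test_that("Mann-Whitney p-values are exact for small untied samples", {
  rq <- rqFrame(A = c(1, 2, 3), B = c(4, 5, 6))
  res <- mannWhitneyPairs(rq)
  expect_equal(res$raw_p, 0.1)      # 2 * 1/C(6,3)
  expect_equal(mannWhitneyPairs(rqFrame(A = c(1, 1, 1),
                                        B = c(1, 1, 1)))$raw_p, 1)
  set.seed(4)
  same <- rnorm(3)
  expect_equal(mannWhitneyPairs(rqFrame(A = same, B = same))$raw_p, 1)
  # invariant to strictly increasing transforms
  set.seed(5)
  rq2 <- rqFrame(A = rexp(3), B = rexp(3) + .5, C = rexp(3) + 1)
  r1 <- mannWhitneyPairs(rq2, c("A", "B", "C"))
  rq3 <- rq2; rq3$rq <- exp(rq3$rq)
  r2 <- mannWhitneyPairs(rq3, c("A", "B", "C"))
  expect_equal(r2$raw_p, r1$raw_p)
})

test_that("Kruskal-Wallis statistic and Dunn gating behave as defined", {
  rq <- rqFrame(A = c(1, 2, 3), B = c(4, 5, 6), C = c(7, 8, 9))
  res <- kruskalDunn(rq, c("A", "B", "C"))
  expect_equal(attr(res, "H"), 7.2)
  # hand Dunn z for fully separated 3x3 ranks: sigma2 = N(N+1)/12 = 7.5
  zAB <- (mean(1:3) - mean(4:6)) / sqrt(7.5 * (2 / 3))
  expect_equal(res$raw_p[1], 2 * pnorm(-abs(zAB)), tolerance = 1e-8)
  # identical groups: omnibus not significant, everything forced to 1
  ties <- rqFrame(A = c(1, 1, 1), B = c(1, 1, 1), C = c(1, 1, 1))
  rest <- kruskalDunn(ties, c("A", "B", "C"))
  expect_true(all(rest$adj_p == 1))
  # omnibus gate: weak separation keeps pairwise at 1
  set.seed(6)
  weak <- rqFrame(A = rnorm(3), B = rnorm(3), C = rnorm(3))
  resw <- kruskalDunn(weak, c("A", "B", "C"))
  if (attr(resw, "omnibus_p") >= 0.05) expect_true(all(resw$adj_p == 1))
  expect_error(kruskalDunn(rqFrame(A = 1:3, B = 4:6)),
               class = "qpcr_too_few_groups")
})

test_that("Holm family-wise error rate is controlled under the global null", {
  set.seed(123)
  nSim <- 10000
  hits <- 0L
  for (i in seq_len(nSim)) {
    rq <- rqFrame(A = rnorm(3), B = rnorm(3), C = rnorm(3))
    if (any(pairwiseTHolm(rq, c("A", "B", "C"))$adj_p < 0.05))
      hits <- hits + 1L
  }
  fwer <- hits / nSim
  upper <- 0.05 + qnorm(0.995) * sqrt(0.05 * 0.95 / nSim)
  expect_lte(fwer, upper)
})
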