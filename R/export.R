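#' Export result tables
#'
#' Writes the full result bundle as plain CSV plus a JSON metadata file:
#' \code{stability.csv} (one row per model and removal level),
#' \code{rq.csv}, \code{stats.csv} (pairwise tests with comparison values),
#' \code{coherence.csv} (per-pair partials and per-gene CS, with a final
#' average-CS row), and \code{run_metadata.json}.  Floats use a fixed
#' format, so re-running the same inputs yields byte-identical files.
#'
#' @param bundle a \linkS4class{CoherenceAnalysis}.
#' @param outputDir directory to write into (created if missing).
#' @return Invisibly, the paths written.
#' @export
exportTables <- function(bundle, outputDir) {
  stopifnot(is(bundle, "CoherenceAnalysis"))
  if (!dir.exists(outputDir) &&
      !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
    .qcStop("unwritable_dir", sprintf("cannot create '%s'", outputDir))

  fmt <- function(df) {
    for (nm in names(df)) if (is.double(df[[nm]])) df[[nm]] <- .fmtNum(df[[nm]])
    df
  }
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outputDir, name)
    write.csv(fmt(df), p, row.names = FALSE, quote = TRUE)
    paths[[length(paths) + 1L]] <<- p
  }

  wr(stabilityRecords(bundle), "stability.csv")
  wr(referenceAssignments(bundle), "references.csv")
  wr(rqValues(bundle), "rq.csv")
  wr(pairTests(bundle), "stats.csv")
  coh <- merge(partialScores(bundle), bundle@coherence, by = "target",
               sort = FALSE)
  coh <- rbind(coh,
               data.frame(target = "average", sample1 = "", sample2 = "",
                          n_models = NA_integer_, partial = NA_real_,
                          cs = averageCS(bundle), stringsAsFactors = FALSE))
  wr(coh, "coherence.csv")

  meta <- c(bundle@config,
            list(package = "qpcrCoherence",
                 version = as.character(packageVersion("qpcrCoherence")),
                 samples = modelUniverse(bundle@modelSpace),
                 n_models = nModels(bundle@modelSpace),
                 average_cs = averageCS(bundle)))
  metaPath <- file.path(outputDir, "run_metadata.json")
  write_json(meta, metaPath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, metaPath))
}

#' Export per-model RQ box-plots
#'
#' One PNG per model (file names sorted by model id): grouped box-plots of
#' RQ per target gene and sample, with red significance bars above sample
#' pairs whose adjusted p-value is below \code{alpha}.  Boxes use the
#' standard convention (median, IQR, whiskers to 1.5 IQR).
#'
#' @param bundle a \linkS4class{CoherenceAnalysis}.
#' @param outputDir directory to write into (created if missing).
#' @param width,height PNG size in pixels.
#' @return Invisibly, the paths written.
#' @export
exportPlots <- function(bundle, outputDir, width = 1400, height = 700) {
  stopifnot(is(bundle, "CoherenceAnalysis"))
  if (!dir.exists(outputDir) &&
      !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
    .qcStop("unwritable_dir", sprintf("cannot create '%s'", outputDir))
  alpha <- bundle@config$alpha
  targets <- bundle@config$targetGenes
  rq <- rqValues(bundle)
  tst <- pairTests(bundle)
  space <- bundle@modelSpace
  nm <- nModels(space)
  paths <- character(nm)
  for (mid in seq_len(nm)) {
    samples <- modelSamples(space, mid)
    m <- length(samples)
    p <- file.path(outputDir, sprintf("model_%03d.png", mid))
    png(p, width = width, height = height)
    op <- par(mar = c(7, 4, 3, 1))
    # x layout: per target a block of m boxes plus one gap
    groups <- list(); at <- numeric(); labs <- character()
    x0 <- 0
    for (tg in targets) {
      for (s in samples) {
        x0 <- x0 + 1
        groups[[length(groups) + 1L]] <-
          rq$rq[rq$model_id == mid & rq$target == tg & rq$sample == s]
        at <- c(at, x0)
        labs <- c(labs, s)
      }
      x0 <- x0 + 1  # gap between target blocks
    }
    ymax <- max(unlist(groups))
    boxplot(groups, at = at, names = labs, las = 2, col = "grey85",
            range = 1.5, ylim = c(0, ymax * (1.35 + 0.1 * m)),
            ylab = "relative quantity (RQ)")
    for (ti in seq_along(targets)) {
      blockStart <- (ti - 1L) * (m + 1L)
      mtext(targets[ti], side = 3, line = 0.2,
            at = blockStart + (m + 1) / 2, cex = 0.9)
      sig <- tst[tst$model_id == mid & tst$target == targets[ti] &
                   tst$adj_p < alpha, , drop = FALSE]
      if (nrow(sig)) {
        for (j in seq_len(nrow(sig))) {
          x1 <- blockStart + match(sig$sample1[j], samples)
          x2 <- blockStart + match(sig$sample2[j], samples)
          y <- ymax * (1.05 + 0.08 * j)
          segments(x1, y, x2, y, col = "red", lwd = 2)
        }
      }
    }
    title(sprintf("model %d: %s", mid, paste(samples, collapse = ", ")))
    par(op)
    dev.off()
    paths[mid] <- p
  }
  invisible(paths)
}
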