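# qpcrCoherence

Selecting a reference ("housekeeping") gene with the lowest stability value
and normalizing against it is the standard way to quantify RT-qPCR data —
and it is not enough.  The same candidate pool can hand different subsets of
your samples different references, and two perfectly defensible
normalizations can then report *opposite* significant changes for the same
target gene in the same two samples.  qpcrCoherence implements a workflow
that detects and repairs exactly this failure mode:

1. **Model space.** From an experimental model of *n* samples, enumerate all
   daughter models — every combination without repetition of ≥ 2 samples
   (for *n* = 5: the experimental model plus 25 daughters, 26 models).
2. **Stability selection.** In every model, estimate each candidate gene's
   expression stability with the model-based inter-/intra-sample variance
   decomposition of NormFinder type, on log2 quantities *y(i,g,j)*
   (gene *i*, sample *g*, replicate *j*): subtract the per-replicate pool
   mean, split the remainder into intergroup variation *d(i,g)* (shrunken by
   the estimated variance γ² of intergroup variation) and intragroup
   variance σ²(i,g) (bias-corrected, clamped at 0), and score
   ρ(i) = mean over g of |d̃(i,g)| + √v(i,g) for single genes, with the
   analogous averaged form for gene pairs.  Lowest ρ wins (single gene or
   pair).
3. **Progressive removal.** Per model, remove the least stable candidate
   (worst single-gene ρ) up to *r* times — never below the 3-gene minimum the
   estimator needs — and optionally keep, per model, the removal level whose
   selected reference was most stable.
4. **Relative quantification.** Normalize every target gene in every model:
   RQ = 2^(Ct_ref − Ct_target), with the pair reference entering as the mean
   of its two Cts.
5. **Statistics.** Compare all sample pairs within each model (pairwise
   pooled t-tests with Holm adjustment by default; Mann–Whitney or
   Kruskal–Wallis + Dunn as non-parametric alternatives).
6. **Coherence score (CS).** Encode each significant comparison as +1/−1 by
   median direction (0 otherwise).  A sample pair is *coherent* (partial
   CS = 1) unless both directions occur across the 2^(n−2) models containing
   the pair.  CS per target gene = mean partial CS over all C(n,2) pairs;
   CS = 1 certifies that the biological conclusion does not depend on the
   model or the normalizer.  The run also reports the average CS across
   target genes.

The package is aimed at anyone validating RT-qPCR normalization across a
panel of samples (cell lines, tissues, conditions): it answers not just
"which reference is most stable?" but "is that stability *good enough* for
the conclusions I am about to draw?".

## Worked example

The built-in generator reproduces the troublesome situation: four candidate
references, one of which ("UNS1") is technically quiet but carries a
+3-cycle expression shift in two of the five samples.

```r
library(qpcrCoherence)

ds <- makeIncoherentScenario(seed = 4)
res0 <- runAnalysis(ds$ct, ds$quant, ds$candidateGenes, ds$targetGenes)
res0
#> CoherenceAnalysis: 5 samples, 26 models, 3 target genes
#> stat method: pairwise_t_holm, alpha = 0.05, remove level 0
#> coherence scores:
#> TGT1 TGT2 TGT3
#>  0.9  0.9  0.9
#> average CS: 0.90
```

A CS of 0.9 means one of the ten sample pairs showed significant expression
differences in *both* directions, depending on which model (and hence which
reference) was used — plain stability selection has produced
self-contradictory biology.  One round of per-model removal of the least
stable candidate, keeping the best level per model, repairs it:

```r
res1 <- runAnalysis(ds$ct, ds$quant, ds$candidateGenes, ds$targetGenes,
                    removeRepetitions = 1, selectBestRemove = TRUE)
res1
#> CoherenceAnalysis: 5 samples, 26 models, 3 target genes
#> stat method: pairwise_t_holm, alpha = 0.05, remove level 1 (best across levels)
#> coherence scores:
#> TGT1 TGT2 TGT3
#>    1    1    1
#> average CS: 1.00
```

`referenceAssignments(res1)`, `stabilityRecords(res1)`, `rqValues(res1)`,
`pairTests(res1)` and `partialScores(res1)` expose every intermediate;
`exportTables(res1, "out/")` and `exportPlots(res1, "out/")` write the CSV
tables, a JSON metadata echo and one RQ box-plot PNG per model.  A thin
command-line front end lives at `inst/cli/qpcrcoherence.R`
(`Rscript qpcrcoherence.R run --ct ct.csv --quant quant.csv --refs ... --targets ...`).

Real analyses read inputs from CSV (`readExpressionTable`): one table of
mean Ct values per biological replicate
(`sample,replicate,<gene1>,<gene2>,...`) for candidates and targets, and one
table of calibration-curve-derived quantities for the candidates.  When no
calibration curve exists, `deriveQuantitiesFromCt()` offers a documented
perfect-efficiency fallback.

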