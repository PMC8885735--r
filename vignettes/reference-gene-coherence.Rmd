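---
title: "Validating RT-qPCR reference genes with model-based stability and coherence scoring"
author: "qpcrCoherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating RT-qPCR reference genes with model-based stability and coherence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrCoherence)
```

# The problem

Relative quantification of an RT-qPCR target gene stands or falls with the
reference gene(s) used for normalization.  The accepted practice — rank a
pool of candidate housekeeping genes by a stability statistic and normalize
against the winner — leaves a blind spot: stability is estimated *within a
set of samples*, so different subsets of the same experiment can
legitimately receive different references, and a reference that looks stable
can still impose its own sample-dependent bias on every target gene.  When
that happens, the *direction* of a significant expression difference between
two samples can depend on which other samples happened to be co-analysed.
No p-value warns about this: each individual analysis is internally sound.

This package treats that cross-model consistency itself as the quantity to
measure.  It runs the entire normalization-and-testing pipeline in every
*model* (subset of two or more samples) of the experiment and scores, per
target gene, whether any sample pair was ever called significant in both
directions.

# The procedure

## Model space

For an ordered universe of $n$ samples, all $\sum_{r=2}^{n} \binom{n}{r}$
combinations without repetition form the model space: the experimental model
(all $n$ samples, always the last model id) and its daughter models.  Models
are numbered size-major, lexicographically by sample position within a size,
so exports are stable across runs.  Every sample pair occurs in exactly
$2^{n-2}$ models.  For the canonical five-sample design this gives 26
models, 10 pairs, 8 models per pair.  The count grows as $2^n$;
`generateModels()` warns above 12 samples (~4000 models), which is far
beyond the intended use case.

## Stability estimation

Within one model, candidate quantities (calibration-curve-derived expression
values, or the documented fallback `deriveQuantitiesFromCt()`) are analysed
on the log2 scale as $y_{igj}$ for gene $i$, sample $g$, replicate $j$.
Samples play the role of groups; biological replicates are the within-group
observations.  The steps:

1. $z_{igj} = y_{igj} - \frac{1}{k}\sum_{i'} y_{i'gj}$ — subtracting the
   pool-gene mean per replicate removes column effects (loading, input
   amount), which makes every stability value exactly invariant to
   rescaling any replicate's quantities by a positive constant.
2. Intergroup variation $\hat d_{ig} = \bar z_{ig} - \bar z_{i\cdot}$.
3. Within-group variances $s^2_{ig}$, bias-corrected for the mean
   subtraction via $\hat\sigma^2_{ig} = \max\!\big(0,\,
   (s^2_{ig} - \hat S_g/k^2)/(1 - 2/k)\big)$ with
   $\hat S_g = \sum_i s^2_{ig}/(1 - 1/k)$.  The correction requires
   $k \ge 3$ candidate genes — the hard minimum enforced throughout — and
   negative small-sample estimates are clamped to zero.
4. Variance of the intergroup variation,
   $\hat\gamma^2 = \max\!\big(0,\, \sum_{ig}\hat d^2_{ig}/((G-1)(k-1)) -
   \sum_{ig} (\hat\sigma^2_{ig}/n_g)/(Gk)\big)$.
5. Shrinkage $\tilde d_{ig} = \hat d_{ig}\,
   \hat\gamma^2/(\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)$ (defined as 0 when
   the denominator is 0).
6. Single-gene stability $\rho_i = \frac{1}{G}\sum_g \big(|\tilde d_{ig}| +
   \sqrt{v_{ig}}\big)$ with
   $v_{ig} = (\hat\sigma^2_{ig}/n_g)\,\hat\gamma^2 /
   (\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)$; pair stability averages the two
   genes' shrunken variation and variances,
   $\rho_{ab} = \frac{1}{G}\sum_g \big(|(\tilde d_{ag}+\tilde d_{bg})/2| +
   \sqrt{(v_{ag}+v_{bg})/4}\big)$.

Lower is more stable; the reference is the arg-min over single genes and
pairs.  Ties prefer a single gene over a pair, then the lexicographically
first name — ties are essentially unreachable with continuous data, but the
rule makes runs reproducible.  One estimator quirk deserves note: whenever
$\hat\gamma^2$ clamps to zero (no detectable intergroup variation relative
to noise, common in quiet two-sample models), *every* $\rho$ collapses to
exactly zero because both terms carry a $\hat\gamma^2$ factor; selection
then falls through to the tie-break rule.  This is the behaviour of the
published estimator, not an artifact of this implementation.

The log base only scales all $\rho$ by a constant and cannot change any
ranking; base 2 is fixed for reproducibility and interpretability (one unit
= one PCR cycle).

## Removal and cross-level selection

`removeRepetitions = r` repeats, per model: estimate single-gene $\rho$ on
the current pool, drop the worst gene (ties: lexicographically last).
Removal is per model — different models may discard different genes — and is
refused when it would leave fewer than 3 genes.  "Least stable" is defined
on single-gene $\rho$, the estimator's per-gene ranking, not on pairs.
With `selectBestRemove = TRUE`, each model's final reference comes from the
removal level (0..r) whose selected reference had the lowest stability
(ties: fewest removals); the per-model chosen stability is then
non-increasing in the removal budget.

## Relative quantification

Targets are quantified from raw Ct values: per replicate,
$RQ = 2^{Ct_{ref} - Ct_{target}}$; a pair reference contributes the
arithmetic mean of its two Cts (the geometric mean on the linear scale).
Perfect efficiency (2) is assumed; no calibrator is applied by default.
Both choices are cosmetic for everything downstream: the comparison values
and CS depend only on p-values and median *ordering*, and both are invariant
to common positive rescalings of a model's RQ values (a `calibrator`
argument exists for presentation parity).  RQ is computed from Ct rather
than from the quantified table because calibration-curve quantities
typically exist only for candidate reference genes.

## Statistics

Within each (model, target) pair, all $\binom{m}{2}$ sample pairs are
tested; the Holm step-down adjustment is applied over exactly that family.
Pooling families across genes or models would couple unrelated analyses.
The default is the classic pooled-variance two-sample t-test on raw RQ
values: with three replicates per group, Welch degrees of freedom are
unstable, and raw-RQ testing matches a normality-of-RQ framing; a
`logRQ = TRUE` switch performs the tests on log2(RQ) instead, since
log-scale testing is also standard practice.  Non-parametric options:
Mann–Whitney (exact two-sided p when both groups have ≤ 8 observations and
no ties, normal approximation with tie correction otherwise; within larger
models it is applied pairwise with Holm adjustment), and Kruskal–Wallis with
Dunn's tie-corrected z-tests, Holm-adjusted and gated on the omnibus test:
if the omnibus p ≥ α all pairwise adjusted p are forced to 1.  Models of two
samples automatically fall back from Kruskal–Wallis to Mann–Whitney, the
recommended test for two unmatched groups.  Degenerate inputs are defined,
not fatal: two constant equal groups give p = 1 (no evidence), constant
unequal groups give the zero-variance limit p = 0, fully tied rank tests
give p = 1.

## Comparison values and coherence

For each (target, pair, model with the pair), the comparison value is 0 if
the adjusted p ≥ α, else +1/−1 by the order of the two samples' median RQ
(the pair itself is always oriented by the fixed universe order).
Significant-but-equal medians map to 0 — unreachable with continuous RQ, but
defined.  By default comparisons use Holm-adjusted p-values, matching a
pipeline that reports adjusted significance; `useAdjustedP = FALSE` switches
to raw p for sensitivity analysis.  A pair's partial CS is 0 iff both +1 and
−1 occur among its $2^{n-2}$ comparisons; the CS of a target gene is the
unweighted mean partial CS over all $\binom{n}{2}$ pairs, and the run-level
average CS is the unweighted mean over target genes.  With $n = 2$ there is
a single model and CS ≡ 1: one analysis cannot contradict itself.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `removeRepetitions` | 0 | removal rounds r (genes); pool − r ≥ 3 enforced |
| `selectBestRemove` | FALSE | per model, keep the level with lowest stability |
| `alpha` | 0.05 | two-sided significance level for comparisons |
| `statMethod` | pairwise_t_holm | or mann_whitney / kruskal_dunn |
| `logRQ` | FALSE | t-tests on log2(RQ) instead of raw RQ |
| `useAdjustedP` | TRUE | comparisons from Holm-adjusted vs raw p |
| `efficiency` (fallback) | 2 | amplification efficiency in (1, 2] |

The practical loop mirrors the intended use: run at level 0; if any target
has CS < 1, raise the removal level with `selectBestRemove = TRUE` and
re-run; when the pool floor is reached, extend the candidate pool with a new
housekeeping gene and start again.

# The synthetic-data generator

`generateDataset()` draws
$Ct(s, r, g) = \mu(s, g) + \mathcal N(0, sd_g)$ — the standard Gaussian
replicate-noise model for qPCR mean Cts — and derives candidate quantities
as $2^{-Ct}$, max-rescaled per gene.  Defaults emulate the canonical design
of this workflow's motivating study: 5 samples × 3 biological replicates,
4 candidate references, Ct levels around 19–26 cycles.

Two scenario builders give known ground truth:

* `makeCoherentScenario()`: candidates flat across samples, targets strictly
  ordered with a 2-cycle step between adjacent samples, replicate noise 0.1
  cycles.  Separation ≫ noise, so the pipeline should complete with CS = 1
  for every target; the test suite requires this in ≥ 99/100 seeds.
* `makeIncoherentScenario()`: three well-behaved candidates (0.2-cycle
  noise) and one candidate with very low replicate noise (0.1 cycles) but a
  +3-cycle shift in the last two samples.  In models mixing shifted and
  unshifted samples, the biased gene's low noise pulls it into the best
  *pair* (the pair's intergroup term averages, so the bias is not fully
  penalized, while the noise advantage persists), and the contaminated
  reference shifts target RQ by half the bias, 1.5 cycles.  The three
  targets carry true effects of 0.6/0.75/0.9 cycles in the shifted samples —
  below 1.5, so the contaminated models flip the significant direction while
  clean models report the truth.  The effects bracket half of the 1.5-cycle
  distortion so that both the true and the flipped difference are large
  enough to reach significance with three replicates.  The suite requires
  CS < 1 at level 0 with a level-1 improvement in ≥ 90/100 seeds, and the
  biased gene to be the experimental model's worst single gene in ≥ 19/20
  seeds.

What the generator deliberately does **not** emulate: amplification-curve
shape and per-gene efficiencies (inputs are mean Cts), technical-replicate
structure (assumed pre-averaged upstream), non-Gaussian outliers, missing
wells, and between-gene correlation of replicate noise.  Passing the
synthetic tests therefore demonstrates that the machinery detects and
repairs reference-induced contradictions under idealized noise; it does not
certify performance on data violating those assumptions.

# Numerical choices and edge cases

* Negative variance estimates (bias correction, $\hat\gamma^2$) clamp to 0.
* $0/0$ in the shrinkage factor is defined as 0 (degenerate zero-variance
  input then yields $\rho = 0$ everywhere).
* Tie-breaks: reference selection single-first then lexicographic; removal
  lexicographically last; cross-level selection lowest level.
* Exported CSV floats use a fixed `%.10g` format, so identical inputs give
  byte-identical files; `writeExpressionTable()` uses 17 significant digits
  so a write/read round trip is bit-exact.
* Missing cells are rejected, never imputed — the decomposition assumes
  balanced complete data.  Errors carry machine-readable condition classes
  (`qpcr_incomplete_table`, `qpcr_pool_exhausted`, ...) naming the offending
  coordinates.

# Problem sizes in the test suite

The suite runs the full pipeline on 5-sample/3-replicate datasets (26
models), sweeps 100 seeds per scenario, checks estimator equivalence
against an independent loop implementation of the formulas on 24 random
fixtures ($k \in \{3,4,5\}$, $G \in \{2,3\}$, 3 replicates, tolerance
1e−6), recomputes CS by brute-force subset enumeration for $n \le 4$, and
estimates the Holm family-wise error rate from 10,000 null simulations of a
3 × 3 design.  `scripts/acceptance.R` re-derives the same quantities from a
single `--seed`.

# Limitations

* Stability values depend on the candidate pool (the pool mean is
  subtracted), so $\rho$ from different pools are not directly comparable —
  only within a (model, pool, level).
* The coherence score certifies *consistency*, not correctness: a reference
  set that is biased in the same way in every model can be coherent and
  wrong.  CS = 1 is necessary, not sufficient, for trustworthy
  normalization.
* All models reuse the same replicate measurements, so the per-model tests
  are not independent; CS is a descriptive consistency index, not a
  p-value.
* Efficiency is assumed perfect (2) in the RQ and in the quantity fallback;
  efficiency-corrected quantification with per-gene standard curves is out
  of scope, as is stability estimation for designs without biological
  replication ($n_g \ge 2$ required).
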