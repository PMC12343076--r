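---
title: "Differential expression in nested single-cell data: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential expression in nested single-cell data: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical content:
the mixed-effect view of pseudoreplication, the three implemented tests,
the count simulator and its calibration, the evaluation metrics, and the
design decisions taken where more than one reasonable choice existed.

## 1. Pseudoreplication in nested designs

Single-cell experiments sample twice: first biological samples, then
cells within each sample. For a gene, expression of cell $j$ in sample
$i$ under condition $c$ is modelled as

$$Y_{cij} = \mu_{c} + b_{ci} + \varepsilon_{cij},\qquad
b_{ci} \sim \mathcal N(0, \sigma_b^2),\quad
\varepsilon_{cij} \sim \mathcal N(0, \nu_\varepsilon^2),$$

all effects independent. Two cells of the same sample share $b_{ci}$ and
are correlated with intraclass correlation
$\rho = \sigma_b^2 / (\sigma_b^2 + \nu_\varepsilon^2)$ (`icc()`). The
variance of the difference in condition means over $N$ samples of $n$
cells each is

$$\mathrm{Var} = \frac{2}{Nn}\,(\sigma_b^2 + \nu_\varepsilon^2)\,
\bigl(1 + (n-1)\rho\bigr)$$

(`varDiffMeans()`). The multiplier $1 + (n-1)\rho$
(`varianceInflation()`) is what a cell-level test silently sets to 1;
at $n = 1000$, $\rho = 0.05$ it is 50.95, and the cell-level t-test
claims $2Nn - 2$ degrees of freedom where only $2N - 2$ independent
units exist (`degreesOfFreedom()`).

`empiricalICC()` estimates $\rho$ from data as per-gene one-way ANOVA
ICC(1) with samples as groups, on log1p-CPM values by default, using the
$n_0$ correction for unbalanced group sizes and clipping to
$[-1/(n_0-1), 1]$; the pooled estimate is the median over genes.
**Batch stratification.** In multi-batch designs the one-way estimator
would absorb the (large, separately modelled) batch shifts into the
between-sample variance and report mostly batch separation rather than
sample-level heterogeneity. `empiricalICC()` therefore computes ICC(1)
within each batch and combines the per-gene estimates as a
cell-count-weighted mean; with a single batch this is exactly the plain
one-way estimator. Samples with one cell carry no within-sample
variance and are excluded with a warning.

## 2. The three tests

All three tests compare means of **log1p-CPM** expression. This scale
choice matters: on the linear CPM scale a down-regulated gene's
difference in means is bounded by its base mean, so down-regulation is
systematically drowned by multiplicative batch noise while
up-regulation is not. The log scale treats a $k$-fold change
symmetrically in both directions. `"cpm"` and raw modes remain
available for sensitivity analyses.

**Pseudobulk permutation test** (`permutationTest()`). Counts are
summed per sample (`pseudobulk()`), normalized, and the observed
statistic per gene is the difference in means between the two sample
groups. The null is built by reshuffling the sample-level labels; the
two-sided p-value is the fraction of assignments whose $|\Delta|$
reaches the observed one. When the number of distinct assignments
$\binom{S}{S_1}$ is at most `exhaustiveThreshold` (default 20 000), all
of them are enumerated — the observed assignment is then part of its own
null, so $p \ge 1/n$ holds by construction; otherwise `nPerm` (default
10 000) Monte-Carlo shuffles are drawn and $p = \max(b, 1)/n$. The
floor $p = 1/n$ is the smallest p-value the test can produce, which is
why `DEResult` records `n_resamples_used`.

**Hierarchical bootstrap** (`hierarchicalBootstrap()`). Each iteration
resamples the hierarchy within each condition: per batch stratum, as
many samples as the stratum holds are drawn with replacement, then
`cellsPerDraw` (default 100) cells with replacement per drawn sample.
Batch representation is equalized by truncating every batch's pool to
the smallest pool within that condition, implementing "equal cells per
batch category"; the equalization is applied within each condition
separately, so conditions with different stratum sizes can pool
different totals. Per iteration the per-gene means of the two pooled
draws are compared; over $n$ iterations, with $c_1$ wins for condition
1 and $c_2$ for condition 2 (exact ties count toward neither),
$p = \max(\min(c_1, c_2), 1)/n$. All-tie genes (e.g. all-zero) get
$p = 1$. Genes that hit the floor after `nBootInitial` (default
10 000) iterations are re-run at `nBootEscalated` (default 100 000) —
adaptive sampling that spends iterations only where resolution is
needed. The reported p is the smaller exceedance fraction as such, not
doubled; it is deliberately the directional formulation, and the
`DEResult` floor invariant refers to the final iteration count. A batch
present in only one condition supports no within-batch comparison and
is excluded from both conditions with a warning.

**Cell-level Welch t-test** (`cellTTest()`). The pseudoreplication
baseline: Welch's two-sample t-test across cells, vectorized over
genes. Zero-variance genes with equal means get $p = 1$; with unequal
means the statistic degenerates and the smallest representable p is
reported. Its p-values are expected (and observed, in the tests) to be
anti-conservative on null data with $\rho > 0$.

## 3. The simulator

`simulateScenario()` generates negative-binomial counts over a nested
design:

1. gene base means $\lambda_g \sim$ Gamma(shape 0.6, rate 0.3);
2. a `de_fraction` subset of genes (5% by default) receives a fold
   change on the condition-2 mean, drawn log-normally with
   natural-scale mean 13.2 and sd 5.5 via moment matching
   (`lognormalParamsFromMoments()`; 5%/95% quantiles ≈ 6.3/23.5), and a
   random direction — up or down with probability 0.5, down meaning the
   reciprocal factor;
3. a per-gene × sample multiplicative log-normal effect with log-scale
   sd `sample_effect_sd` induces within-sample correlation;
4. per-gene × batch multiplicative factors: magnitudes log-normal with
   the batch's (location, scale) — defaults (0.05, 0.1), (0.8, 0.1),
   (1.45, 0.05) for the three-batch presets — and direction (factor vs
   reciprocal) random per gene and batch. Because directions are
   random, batch separation is a property of the factor *magnitudes*:
   per gene, $|\log$ factor$|$ orders like the locations for ≳ 99% of
   genes, which is what the batch-separation test checks;
5. per-cell expected counts: the sample's gene means normalized to
   proportions, times a log-normal library size (location 11, scale
   0.2);
6. counts $\sim$ NB with variance $\mu + \mathrm{bcv}^2\mu^2$,
   `bcv_common` = 0.1.

Presets: `dataset` (1 batch, 2 × 5 samples × 250 cells),
`atlas` (3 batches × 5 samples × 250 cells; five samples cannot split
evenly between two conditions, so batches split 3/2 with the majority
condition alternating, keeping every batch two-conditioned and the
global split 8/7), `varying_cells` (dataset layout with
gamma(0.8, 0.0035) cells per sample, rounded and floored at 10 — the
gamma mass near zero would otherwise produce cell-less samples),
`unbalanced_atlas` (two batches, 9:1 and 1:9), and `negative_control`
(atlas layout, `de_fraction = 0`).

**Calibration.** `sample_effect_sd` defaults to 0.13, chosen once so
that the pooled batch-stratified empirical ICC(1) of a default-scale
negative control sits near 0.05 — a realistic magnitude for
between-sample heterogeneity; the tests verify the pooled estimate
falls in [0.02, 0.12] and collapses to ~0 when the effect is switched
off. Note the empirical ICC of count data depends on sequencing depth
per gene (cell-level NB noise shrinks as counts grow), so the pooled
value drifts upward at smaller gene counts for the same
`sample_effect_sd`.

**What the simulator does and does not emulate.** It reproduces the
nested correlation structure, multiplicative batch effects, variable
cell counts and log-normal DE fold changes. It does not model
zero-inflation beyond NB sampling (current evidence does not support
extra zero-inflation for UMI data), cell-type mixtures, doublets, or
empirical library-size distributions; with the gamma/log-normal
defaults above, per-gene counts are comparatively deep, so simulated
data are *cleaner* than typical droplet data. Passing benchmarks
therefore demonstrate the correctness and relative behaviour of the
machinery under the stated conditions, not absolute real-data
performance; on real data all methods' scores would be far lower.

## 4. Evaluation

`prCurve()` ranks genes by ascending p, ties broken by decreasing
|effect| and then gene id (a deterministic total order, also used by
`topGenes()` and `jaccardTopN()`), sweeps all rank cutoffs, and
integrates by step-wise average precision — no interpolation, which
would bias the area upward. The random-ranking baseline equals the
prevalence, with a small positive finite-size bias of order $1/G$.

`calibrationCurve()` reports observed FPR over a grid of p-value
cutoffs (default 2000 equidistant in (0, 1]). One subtlety the tests
encode: on a negative control all genes share a single label
assignment, so per-dataset curves tilt together — a batch-balanced
assignment makes every gene conservative, an unbalanced one the
opposite. The randomization guarantee of the permutation test is
*marginal* over label assignments; calibration is therefore assessed by
assigning labels via `permuteConditionLabels()` and pooling p-values
over independent replicates, mirroring a repeated-simulation protocol.

`splitDataset()` partitions cells into ≤ `maxCells` subsets keeping at
least `minCellsPerSample` cells of every sample in every subset,
dealing each sample's shuffled cells round-robin with a continued
offset (so subset totals differ by at most one cell); infeasible
constraint pairs reduce the subset count with a warning or are
rejected. `runBenchmark()` ties simulation, the 10% detection filter
(genes detected in fewer than 10% of cells are removed; a gene at
exactly 10% is retained), testing and AUPRC into a tidy table, with
per-replicate seeds derived from a base seed.

## 5. Problem sizes and numerical choices

- The shipped tests and the acceptance script run the scenario
  benchmarks at 1000 genes, 5 replicates, and 1000 initial bootstrap
  iterations (escalated ×10) — sizes chosen so the whole suite runs in
  minutes on a laptop while keeping Monte-Carlo error well inside the
  assertion tolerances. The method defaults (10 000/100 000
  iterations, 10 000 permutations) are the full-scale settings.
- Permutation and exhaustive-enumeration statistics are compared with a
  tolerance of $10^{-12}$ so floating-point noise cannot flip a tie.
- `bhAdjust()` validates p ∈ (0, 1] and delegates to the standard BH
  step-up.
- All randomness flows through explicit `seed` arguments
  (`withr::with_seed`), so every result in this package is exactly
  reproducible; the global RNG state is never touched.

## 6. Known limitations

- The simulator's noise levels follow published defaults of standard
  count simulators rather than being fitted to a specific tissue or
  platform; absolute AUPRC values are optimistic (see §3) even though
  relative method behaviour (batch-aware resampling helping on
  unbalanced designs, t-test miscalibration on correlated nulls) is
  informative.
- The hierarchical bootstrap's directional p-value is anti-conservative
  by construction near the floor; treat its p-values as a ranking
  device rather than calibrated error rates (the calibration tests
  quantify this on null data).
- `empiricalICC()` assumes the batch and sample labels are correct;
  unmodelled covariates (cell type composition, sex) load onto the
  sample variance and inflate the estimate.
- External methods are supported only through their result tables
  (`readDEResult()`), not wrapped or re-implemented.
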