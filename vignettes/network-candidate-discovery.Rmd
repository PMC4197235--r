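---
title: "Network-based discovery of early transcriptional responses to cardiac injury"
author: "cardioNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based discovery of early transcriptional responses to cardiac injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioNet)
```

# The problem

Adult zebrafish regenerate their myocardium after severe injury, which makes
time-course expression profiling of injured hearts a natural screen for genes
that drive tissue repair. A typical design measures log2 expression on
microarrays at a control/sham condition and several days post-injury (dpi),
with few biological replicates per time point. Single-gene tests on such
designs are noisy, and any individual network method has its own failure
modes; the strategy implemented here therefore combines one differential
expression stage with three *independent* network analyses and two
*independent* validation layers (a second expression dataset, and qPCR in a
different injury model), and nominates genes supported by at least one
technique and, ideally, reproduced across datasets.

`cardioNet` implements that whole chain as composable functions plus a
`runPipeline()` orchestrator, and ships a synthetic-data generator with
planted ground truth so every stage can be exercised and quantitatively
validated without any external download.

# Stage by stage

## Moderated differential expression

Features that never exceed log2 expression 6 in any sample are removed first
(`filterLowExpression()`); they cannot be informative and cost multiple-testing
power. The retained matrix is fit per feature with condition-mean least
squares; residual variances $s^2_g$ (df $d_g$) are shrunk toward a common
prior by the standard empirical-Bayes moment estimator: fitting a scaled F
distribution to the $s^2_g$ via the mean and variance of $\log s^2_g$ and
digamma/trigamma inversion yields $(d_0, s_0^2)$, and posterior variances
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ give moderated t
statistics per day-vs-control contrast and a moderated omnibus F across the
four contrasts. The computation is delegated to `limma`; the test suite
re-derives the closed-form statistics independently and requires agreement to
1e-10. When the moment equations have no positive solution the estimator
falls back to complete pooling ($d_0 = \infty$, prior = mean sample
variance).

"Variable across time points" can mean the omnibus F or the union of
per-contrast calls; both counts are reported by `countSignificant()`, and the
omnibus is the default everywhere else. Gene-level bookkeeping excludes
unannotated features, and probe multiplicity is collapsed for network stages
by keeping, per gene symbol, the probe with the smallest omnibus raw p — a
deterministic rule chosen because probe-level networks would double-count
genes.

## Co-expression network with a MIC confirmation

Among the top differentially expressed genes (omnibus FDR below 1e-4, capped
at the 100 strongest, mirroring the scale of a top-gene set) all pairwise
Pearson correlations are computed; an edge requires $|r| \ge 0.95$ **and**
maximal information coefficient above 0.95. The boundary semantics are
deliberate: the $r$ gate keeps equality (edges with $|r| < 0.95$ are
discarded), the MIC gate is strict.

MIC is the grid-maximised normalised mutual information
$\max_{ab \le B(n)} I_{a\times b}(x,y)/\log_2 \min(a,b)$ with
$B(n) = \max(n^{0.6}, 4)$; the floor of 4 is required for any $2\times 2$
grid to exist at small $n$ and matches reference implementations. Grid lines
may only separate distinct data values. For each row count the implementation
enumerates all row partitions exhaustively whenever their number is modest
(always true at microarray sample sizes, where $B(n) \le 5$ admits only
$2\times2$ grids), and finds the exactly optimal column partition for each by
dynamic programming; both orientations are searched. This makes the estimator
*identical* to full grid enumeration at small $n$ — the property the test
suite asserts at 1e-9 — while the classic equipartition heuristic is retained
as a fallback for large $n$, where exhaustive enumeration would explode. The
published clump-factor approximation is unnecessary under this scheme and is
not implemented. One arithmetic consequence worth knowing: on strictly
monotone data MIC is exactly 1 only when $n$ is even; at $n = 15$ the best
$2\times2$ split is 7|8 and MIC $= H(7/15) \approx 0.9968$.

## Cohesive overlapping modules

Modules are grown greedily from unused seeds (highest degree first, ties
lexicographic) under the cohesiveness objective
$f(V) = w_{in}/(w_{in} + w_{bound} + p\,|V|)$ with node penalty $p = 2$,
applying whichever single node addition or removal most increases $f$ until
none does. Grown groups with match score
$\omega(A,B) = |A \cap B|^2/(|A||B|) \ge 0.8$ are merged on connected
components of the overlap graph, iterated to a fixpoint so the outcome cannot
depend on pair order. Modules smaller than 5 nodes or below the density
threshold (0.5 in "auto" mode for unweighted networks) are dropped; the
haircut parameter is retained for fidelity and is a no-op at its default 0.
Module quality is scored by a one-sided Mann–Whitney test comparing in-module
versus out-of-module edge weight sums over boundary vertices. The original
plugin's exact null is undocumented, so these p-values should be read as a
separation score rather than a calibrated probability.

## Directed model-tree network

Each gene in turn is the target of an M5'-style model tree over the remaining
genes: splits maximise the standard-deviation reduction
$SDR = sd(T) - \sum_i \frac{|T_i|}{|T|} sd(T_i)$, stopping below 5% of the
root sd or 2×`minLeaf` samples (`minLeaf` 4). Node models are least-squares
fits simplified by best-drop backward elimination under the penalised error
$\bar{|e|}\,(n + 2v)/(n - v)$; pruning collapses a subtree whenever the node
model does at least as well as the subtree, with the subtree charged for its
leaf parameters *and* one parameter per split — without that charge a chance
split always looks cheaper than it is. Predictions are smoothed along the
root path with the classic $k = 15$ blending.

Hypothetical evidences for a retained target (tree relative error
$\le \theta = 0.30$, relative error being mean absolute residual over mean
absolute deviation) are the predictors appearing in leaf models, plus any
predictor whose single-predictor linear model over all samples also meets
$\theta$. The second rule is the method's global-similarity mode and it
matters in practice: co-regulated genes are near-collinear, and which of them
survives model simplification is essentially a coin flip at $n = 15$, while
the set of genes that individually explain the target is stable. Each
evidence is tested by the two-sided correlation t-test (df $n-2$),
Benjamini–Yekutieli adjusted jointly (valid under the strong dependence such
networks exhibit), and kept below $\alpha = 0.05$. The reported slope is the
pairwise regression of target on predictor — the per-edge linear model — and
its sign yields the UP/DOWN direction label.

A limitation inherited from SDR splitting: on an exactly symmetric
piecewise-linear target (equal and opposite slopes meeting at the midpoint)
the two halves have identical value distributions, so no single split
reduces the sd and the breakpoint is only localised indirectly; the pure
regions still recover their slopes exactly after pruning.

## Weighted topological-overlap modules

On the wider FDR < 0.05 gene set, adjacency is
$a_{ij} = |\rho_{ij}|^{\beta}$ with Spearman correlation
(pairwise-complete) and soft power $\beta = 10$; the topological overlap
$TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$
re-weights pairs by shared neighbourhood, and $1 - TOM$ feeds average-linkage
hierarchical clustering. The dynamic hybrid cut is implemented in a reduced,
fully documented form: branches are never joined above the 0.99 height cap;
below it a branch splits into its two children whenever both could stand as
modules of at least `minModuleSize` = 20 genes (recursively); leftover genes
join their nearest module by average TOM distance only if they lie no
farther from it than the module's farthest current member. The published
heuristic's core-scatter machinery is omitted — it has several unstated
constants — so module boundaries on real data can differ from the original
tool's, and attempts to reproduce exact printed module sizes should expect
divergence from this source.

Module eigengenes are first principal components of the row-standardised
module submatrix, sign-oriented to correlate positively with the module mean
profile (PCs are sign-ambiguous; signed module membership only makes sense
after fixing an orientation). Modules with eigengene dissimilarity
$1 - cor < 0.15$ are merged iteratively. Module membership is
$MM_g = cor(x_g, E_{m(g)})$ with the same correlation type, with p from
$t = MM\sqrt{(n-2)/(1-MM^2)}$; negative MM is meaningful and reported.

## Cross-dataset concordance and candidate selection

Between two studies, per-gene condition-mean profiles over the matched
conditions (control, 1, 3, 5 dpi — four points) are correlated; genes with
$r > 0.8$ are flagged concordant. Condition means, not per-sample values,
are used because the companion design is replicate-unbalanced, making
per-sample pairing ill-defined. With only four points the null rate of
$r > 0.8$ is appreciable (~10%), which is why concordance is one voting
technique among four rather than a filter. Gene matching is by symbol,
case-insensitive, after probe collapse. Fold-change concordance between any
two sources (arrays, qPCR, external tables) is a plain Pearson correlation
over paired per-gene log2FC with its t-test p.

`selectCandidates()` takes the union of genes flagged by (a) membership in a
significant cohesive module, (b) the directed network, (c) |MM| ≥ 0.8 in a
weighted module, (d) cross-dataset concordance, applies manual include /
exclude lists, and ranks by omnibus FDR then flag count. The inclusion
criteria that are human judgments — prior functional characterisation,
primer design feasibility — are deliberately *not* inferred from data; they
enter only through the config lists, and manually added genes are labelled
as such.

## qPCR validation

Relative quantities use the efficiency-corrected ΔΔCq rule
$RQ = E^{\,\bar{Cq}_{cal} - Cq}$ per gene with its own primer efficiency
$E \in (1, 2]$ (percent input accepted). Technical duplicates are averaged on
the Cq scale; per sample a normalisation factor is the geometric mean of the
three reference-gene RQs (*ef1a*, *rpl13a*, *tuba1*), and biological
replicates are averaged on the log2 normalised scale — Cq-scale averaging for
technical and log-scale for biological replication is the standard ΔΔCq
order, chosen here because instrument software leaves it unspecified.
Standard errors come from replicate variability of the two arms. The key
invariant: a loading difference that multiplies every transcript of a sample
by a common factor shifts each gene's Cq by $\log_E$ of that factor and
cancels exactly through the geometric-mean normalisation, whatever the mix of
per-primer efficiencies.

# What the generator emulates — and what it does not

`simulationConfig()` defaults define the study conditions used throughout the
tests and the acceptance script:

* 5 conditions (control, 1/3/5/7 dpi) × 3 replicates; companion design
  control/1/3/5 dpi with 4/1/2/2 replicates (the second deposited dataset's
  unbalanced shape).
* 1200 genes with 1–2 probes each; half of all genes pinned below the log2
  = 6 floor, emulating the roughly half of array features removed by
  pre-filtering.
* 25% of the remaining genes differentially expressed with per-condition
  effects of sd 2 log2 units; biological replicate variability of 0.35 and
  measurement noise of 0.3 log2 units; probe offsets of 0.2.
* Two planted co-expression modules (18 and 21 genes — the sizes of the two
  reported cohesive modules) built from the latent model
  $x = \sqrt{\rho}\,L + \sqrt{1-\rho}\,Z$ at $\rho = 0.95$ and scale 1.5,
  with early-up and late-up time profiles; the latent adds a within-condition
  jitter of 0.25 around its profile, the module's shared biological
  variability.
* A signed hub: *ptgis* with a strong early-induction profile and dependents
  *ca2* (positive), *usp2a*, *sgce*, *acta1a* (negative), residual sd 0.25 —
  the four signed associations the validation experiments probed.
* qPCR Cq tables with per-primer efficiencies, technical duplicates, a
  log-normal per-sample loading factor, and three stable reference genes.

Not emulated: probe-level CEL intensities, normalisation and summarization
artifacts, spatial effects, batch structure, count-type (RNA-seq) noise, and
annotation ambiguity beyond simple probe multiplicity. Passing the recovery
tests therefore says the *methods* are implemented correctly and are powered
for effects of the planted kind; it does not certify performance on data
whose dominant noise is of a kind the generator does not produce.

# Numerical choices and problem sizes

Tie-breaks are deterministic everywhere (lexicographic gene ids; additions
preferred over removals in module growth; best-drop elimination). Constant
genes yield NA correlations and are excluded from edges; MIC of a constant
vector is 0; a zero-variance tree target has relative error 0 by convention.
All simulation-driven checks run at the scale the design implies: 15 (or 11)
samples, hundreds to 2000 genes, 20 Monte-Carlo seeds per recovery claim;
the full pipeline on the default 1200-gene configuration completes in well
under a minute. The test suite asserts, among others: empirical FDR at or
below nominal on nulls, ≥ 95% planted-DE recovery, exact MIC/TOM agreement
with brute-force enumeration, ≥ 0.8 Jaccard / adjusted Rand recovery of
planted modules, ≥ 18/20 signed hub recovery, exact noiseless ΔΔCq round
trips, and byte-identical pipeline reruns.

# Known limitations

* The cohesive-module p-value approximates the original plugin's
  undocumented null; printed significance levels from that tool are not
  directly comparable.
* The reduced dynamic cut reproduces planted block structure but not
  necessarily the exact module counts a full core-scatter implementation
  would produce on real data.
* MIC at large $n$ falls back to the equipartition heuristic on the
  enumerated axis and is then a lower bound on the exhaustive value, as all
  practical MIC estimators are.
* The directed network's edge significance uses the marginal correlation
  test; genes explained only conditionally (never marginally) are not
  scored, and the global-evidence rule adds edges for every strong marginal
  dependency of a well-modelled target, which errs on the inclusive side.
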