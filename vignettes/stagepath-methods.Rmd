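---
title: "Methods: stage-aware co-expression pathway deviation and diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-aware co-expression pathway deviation and diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagepath)
```

# Scope

`stagepath` implements a pipeline for finding pathways whose coordinated
expression deviates early in tumour development, and for turning those
pathways' genes into a diagnostic classifier. The input is a genes ×
samples expression matrix with each sample labelled `control`, `early`
(stage I) or `late` (stage II–IV). The pipeline has six stages:

1. preprocessing (missing-value handling, control-referenced z-scores);
2. stage-specific differential expression (moderated t);
3. phase-wise Pearson co-expression networks and their topology;
4. sigmoid degree weights;
5. permutation-calibrated pathway deviation scores and ANOVA screening;
6. SVM recursive feature elimination and cross-validated evaluation.

Every stage is exposed as a plain function over matrices and data
frames; the `StageExperiment` class (a `SummarizedExperiment` with
validated phase/stage labels) is a convenience container, not a
requirement.

# Model and assumptions

## Normalization

Expression is standardized per gene against the **control group only**:

$$z_{gs} = \frac{x_{gs} - \bar{x}_{g,\mathrm{ctrl}}}{\mathrm{sd}(x_{g,\mathrm{ctrl}})}$$

so that a cancer sample's z-value reads directly as "standard deviations
away from normal". The control sd uses the unbiased $n-1$ convention,
and at least two control samples are required. Before normalization,
`filterMissing()` removes genes missing in strictly more than 10% of
samples, then samples missing in strictly more than 10% of the surviving
genes (in that order — the two passes do not commute and the gene pass
runs first); remaining gaps are filled with the gene's observed mean by
`imputeMissing()`.

`computeCV()` (coefficient of variation, sd/mean over the cancer
samples) and `cvFilter()` (keep the top-50% of |CV|) are provided for
variability filtering of **raw-scale intensities**. The CV is not
scale-invariant: on control-referenced z-scores, unaffected genes have
means near zero and therefore arbitrarily large |CV|, so a top-|CV|
filter on normalized data preferentially *discards* shifted genes. For
this reason the worked pipelines in this package run differential
expression on all genes and reserve the CV filter for raw intensity
matrices, where it measures biological variability as intended.

## Differential expression

`differentialExpression()` computes, per gene, the difference of group
means (the effect, reported as `log_fc` under the convention that the
input is already on a log-like or standardized scale) and a moderated
t-statistic: per-gene variances are shrunk toward a common prior fitted
by moment matching of the scaled-F model for sample variances
($s_g^2 \sim s_0^2 F_{d, d_0}$), giving

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d s_g^2}{d_0 + d}, \qquad
  t_g = \frac{\Delta_g}{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}}$$

on $d + d_0$ degrees of freedom. With `shrink = FALSE` the statistic is
exactly the pooled two-sample t-test. The moment-matching prior is a
deliberate re-derivation rather than a call to an external package; the
test suite cross-checks it against `limma::eBayes` (agreement of
p-values to within 0.05 absolute, correlation > 0.995, and > 98%
concordance of calls at 0.05 — the residual difference is the prior
estimator, which limma fits by matching log-variance moments).

Three gene sets follow (`extractStageSets()`, at p < 0.05 and
|effect| ≥ 1): the early-versus-control set, the late-versus-control
set, and their id-intersection (the "shared" set), which retains each
gene's direction in both comparisons. The shared set is the node
universe of the non-specific co-expression network and the query for
`fisherEnrichment()` (hypergeometric upper tail).

## Co-expression networks and topology

`pairwiseCorrelation()` computes Pearson correlations over a chosen
sample window; `classifyPairs()` labels a pair positive/negative when
|r| strictly exceeds the threshold (default 0.5 — a pair at exactly the
threshold is unclassified). Phase-specific networks use the same node
universe and differ only in which phase's samples supply the
correlations, which makes their topologies directly comparable;
`stablePairs()` extracts the pairs classified with the same sign in
every phase.

`topologyMetrics()` reports, on the unweighted undirected graph:
average shortest path (mean geodesic over ordered reachable pairs),
degree, closeness, and the local clustering coefficient. Because these
networks are typically fragmented, closeness uses the Wasserman–Faust
correction,

$$C(v) = \frac{r_v}{\sum_{u} d(v, u)} \cdot \frac{r_v}{n - 1},$$

with $r_v$ the number of nodes reachable from $v$ (isolated nodes get
0), and the average shortest path ignores unreachable pairs. Shortest
paths, degree and clustering are delegated to `igraph`; the test suite
verifies them against an independent breadth-first-search oracle.

## Degree weights and the pathway deviation score

Each gene's network degree is mapped to a weight through the logistic
sigmoid $w_g = 1/(1 + e^{-\deg(g)})$ (`degreeWeights()`), so hub genes
count more. Genes in the scoring universe but absent from the network
receive the minimum in-network weight. A "sigmoid with gain zero" would
weight every gene 0.5 regardless of degree; the package instead uses
unit gain, and an empty network falls back to 0.5 everywhere with a
warning.

Per gene, a one-way ANOVA F-test across the three phases
(`geneAnova()`) yields a p-value, converted to a weighted Z
(`pToZ()`): $Z'_g = w_g \, \Phi^{-1}(1 - p_g)$, with p floored at
1e-16 so Z stays finite. A pathway's raw deviation score over its
differentially expressed members' $Z'$ values is the running-mean
maximum (`deviationScore()`):

$$A(P) = \max_{1 \le t \le |P|} \frac{1}{\sqrt{t}} \sum_{i=1}^{t}
  Z'_{(i)}, \qquad Z'_{(1)} \ge Z'_{(2)} \ge \dots$$

which rewards a coherent strongly-deviating subset without diluting it
by the pathway's full size; ties in the maximizing prefix resolve to
the smallest $t$. Because $A$ grows with set size even under the null,
`calibrateScore()` standardizes it against `nPerm` random gene sets of
the same size drawn without replacement from the background Z pool:
$A_\mathrm{corrected} = (A - \mu_k)/\sigma_k$. `scorePathways()` gives
each pathway its own RNG stream derived by hashing the pathway name
into the master seed, so scores do not depend on evaluation order and
adding or removing pathways leaves the others' scores bit-identical.

`sampleScores()` applies the same max-prefix statistic to each
*sample's* weighted normalized expression over the pathway members,
yielding one score per sample; `pathwayAnova()` then screens those
per-sample scores across the three phases. Both readings — the
gene-level calibrated score and the per-sample profile — are exposed,
because phase-wise screening needs a per-sample quantity while
calibration is defined at the gene level.

## Diagnostic model

`makeLabels()` derives binary labels (stage I/II versus III/IV,
control versus cancer, or early versus late). `rfeSelect()` performs
recursive feature elimination: a linear-kernel SVM ranks the surviving
features by absolute weight ($w = \sum_i \alpha_i y_i x_i$), the lowest
is eliminated, and at each size the stratified cross-validated accuracy
of an RBF-kernel SVM on that feature set is recorded; the selected set
maximizes the curve, ties resolved toward fewer features. The linear
kernel is used only for ranking (RBF SVMs have no per-feature weight
vector); model quality is always measured with the RBF kernel.
`trainSvm()` grid-searches (cost, gamma) by stratified CV accuracy with
deterministic tie-breaking toward smaller cost then smaller gamma; the
default gamma grid is centred on `1 / (n_features × mean feature
variance)` — a "gamma of 0" is not a usable RBF parameter, so the
data-scaled centre stands in for the conventional default.
`evaluateCv()` reports mean per-fold accuracy and a trapezoidal AUROC
computed from the SVM decision values (cross-checked against `pROC` in
the test suite). The underlying SVM solver is `e1071` (libsvm); the
RFE loop, ranking, grid search and ROC integration are implemented
here.

# The synthetic data generator

`simulateStageData()` produces a genes × samples matrix with known
ground truth, returned in `$truth`:

* background: independent standard normal per gene and sample (after
  control-referenced normalization, real intensity data are
  approximately this for unaffected genes);
* planted differential expression: disjoint early-only, late-only and
  shared gene sets receive a mean shift of ±`shift` (sign per gene) in
  the affected phase(s);
* planted co-expression blocks: within a block, samples of a phase
  share a latent factor, $x = \sqrt{\rho} f + \sqrt{1-\rho}\,
  \varepsilon$, giving pairwise correlation ≈ ρ per phase (default 0.1
  in controls, 0.7 in cancer phases — emulating coordination that
  appears with disease);
* pathways: random member sets, except the "deviated" ones, which draw
  at least `deviatedFraction` (default 80%) of their members from the
  shared planted genes;
* `rawScale = TRUE` applies a per-gene affine map to intensity-like
  scales (means ~ U(6, 12), sds ~ U(0.5, 2)), for exercising the
  normalization path.

The generator emulates location shifts and block correlation only. It
does **not** emulate heavy-tailed intensity noise, batch effects,
probe-level artefacts, dependence between differential expression and
correlation structure beyond the planted overlap, or survival
outcomes. Conclusions drawn from it are about the correctness of the
algorithms, not about biological performance.

Default sizes (2,000 genes; 81 control / 28 early / 53 late samples)
are this package's own choice of a desk-scale regime in which every
pipeline stage is exercised and planted effects of modest size (shift
2, sets of 30–60 genes, 50 pathways of 20) are comfortably but not
trivially recoverable.

# Numerical choices

* Control sd uses $n - 1$; a zero control sd is an error, not a silent
  NaN.
* Degenerate ANOVA cases: a totally flat gene gets p = 1; zero
  within-group but positive between-group variance gets p = 1e-300.
* p-values are floored at 1e-16 before the normal-quantile transform.
* The permutation null requires a non-constant background pool
  (σ = 0 is an error) and uses the unbiased sd.
* Pair classification is strict (|r| must exceed the threshold);
  undefined correlations (constant genes) are never classified.
* RFE tie-breaks toward fewer features; the grid search toward smaller
  cost, then smaller gamma — all results are reproducible from seeds.

# Limitations

* Pearson correlation only; rank-based alternatives are not provided.
* The moderated-t prior is moment-matched, so p-values differ from
  `limma`'s in the third decimal place for small samples.
* The per-sample pathway score shares the max-prefix form with the
  gene-level score but has no calibration of its own; it is screened by
  ANOVA, not standardized.
* The classifier assumes a two-class problem with at least two samples
  per class per fold.
* No survival analysis is included.

This vignette states no empirical result beyond what the package's
test suite and `scripts/acceptance.R` compute.
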