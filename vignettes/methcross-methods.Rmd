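---
title: "Direction-aware differential methylation with methcross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direction-aware differential methylation with methcross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(methcross)
```

## The analysis in one paragraph

`methcross` analyses Illumina 450K-style DNA methylation data from a two-group
design (here labelled Control and Periodontitis, the disease the package's
defaults emulate). Beta values — per-CpG methylation fractions in [0, 1] — from
several datasets are merged on shared probes, filtered by missingness,
logit2-transformed to M-values, and screened per CpG with a moderated t-test.
Significant CpGs are then read through a *direction-aware* lens: each group's
mean beta is called high (β ≥ 0.5) or low (β < 0.5), and CpGs whose state
crosses the 0.5 boundary between groups — low-to-high or high-to-low — are
ranked, aggregated per gene, cross-tabulated against CpG-island and
gene-structure annotation, and carried into a hypergeometric
over-representation analysis.

## Differential model

For each CpG $g$, observed beta values are clamped to
$[\varepsilon, 1-\varepsilon]$ (default $\varepsilon = 10^{-6}$, so boundary
betas map to finite values) and transformed to M-values
$M = \log_2\!\frac{\beta}{1-\beta}$, the conventional modelling scale:
M-values are approximately homoscedastic where betas are variance-compressed
near 0 and 1. A group-only linear model is fitted per probe over its observed
entries; the coefficient of interest is
$\mathrm{logFC}_g = \bar M_{g,\text{case}} - \bar M_{g,\text{control}}$, with
pooled residual variance $s_g^2$ on $d_g = n_g - 2$ degrees of freedom and
unscaled coefficient standard deviation
$u_g = \sqrt{1/n_{g,\text{case}} + 1/n_{g,\text{control}}}$ (per-probe
observed counts, so missingness is handled exactly). Probes with fewer than
two observed samples in either group are excluded, with a reported count —
imputation is deliberately avoided.

Variances are moderated by empirical Bayes. The hierarchical model places a
scaled inverse-chi-square prior $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ on
the true variances; $(d_0, s_0^2)$ are estimated by the closed-form moments
match on $\log s_g^2$: after centring each log variance by its sampling
expectation given $d_g$ (digamma terms), the dispersion in excess of the
trigamma sampling floor determines $d_0$ by trigamma inversion, and the mean
determines $s_0^2$. When the observed dispersion does not exceed the floor,
$d_0 = \infty$ and the common-variance estimate $s_0^2 = \overline{s^2}$ is
used. The moderated statistic is

$$\tilde t_g = \frac{\mathrm{logFC}_g}{u_g \sqrt{\tilde s_g^2}}, \qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

referenced to $t_{d_0 + d_g}$ (standard normal at $d_0 = \infty$). Two-sided
p-values receive Benjamini–Hochberg step-up adjustment (implemented
in-package as $\min(1, \min_{j \ge i} m\,p_{(j)}/j)$ via a reverse cumulative
minimum; the test suite checks it against both a brute-force O(m²) oracle and
`p.adjust`), and the significance call is adjusted p < 0.05 by default.
B-statistics (log posterior odds of differential methylation) are reported
from the standard closed form, with prior differential proportion 0.01 and
the prior coefficient variance estimated from the large-|t| tail; they are
informational and nothing downstream keys on them. The whole fit is exposed
as `dmp_fit()`, returning a classed object with `print`, `summary`, `coef`
and `plot` (volcano) methods; the suite cross-checks the entire path against
limma's `lmFit`/`eBayes` on shared data, which serves as an independent
reference, never as the implementation.

Covariates (age, sex, batch) are not modelled: the design is group-only,
matching the integrated-cohort setting the package emulates, where covariates
could not be applied uniformly across datasets.

## Directionality classification

Group-mean betas are computed over observed entries on the *beta* scale (not
back-transformed M means). The state rule is inclusive at the boundary: mean
β ≥ 0.5 is high-methylation, β < 0.5 low. The change class is the pure
function of the two states: `low_to_high`, `high_to_low`, `stable_high`,
`stable_low`; a missing group mean yields an explicit unclassifiable marker.
The (0.5, 0.5) corner is therefore `stable_high`.

Top genes are ranked within each crossing direction among significant
crossing probes. Probe-to-gene mappings are exploded — a probe annotated to k
genes contributes to all k, so genes sharing a probe receive identical
statistics — and per (gene, direction) the qualifying probes' logFC and group
means are averaged. The default ranking key is |mean logFC| per gene: the
published table this output mirrors sorts by its mean-logFC column, so the
per-gene mean is the primary reading; ranking by the single largest per-CpG
|logFC| is available via `rank_by = "max"`. Ties break lexicographically by
gene symbol so output is deterministic.

## Cross-tabulation

The counting unit is the *CpG-feature assignment*: one count per retained
(gene, gene-structure) mapping of a significant probe, one for an unannotated
probe. This makes the strata a true partition — cell counts sum to the total
number of assignments — which a per-probe count cannot achieve once
multi-mappings are retained. All percentages use the total number of
significant assignments as denominator; a published variant of this table
describes a top-20-gene denominator in its legend, but its printed counts are
only consistent with a global denominator, so the global one is used and
documented here. Rows are emitted in fixed category orders (Island, N_Shore,
S_Shore, N_Shelf, S_Shelf, OpenSea, Unknown; TSS200, TSS1500, 5'UTR, 1stExon,
Body, 3'UTR, Unknown). The state column reports the case group's state, so
High-methylation rows pair with the low-to-high crossing. Rendered
percentages use two decimals with `"< 0.01"` for positive values below
0.005; an exactly empty cell prints `0.00`.

## Over-representation analysis

Gene sets are flat sets read from GMT; no ontology-graph semantics. For query
size $n$ in a universe of $N$ genes and a term with $K$ universe genes and
overlap $k$, the p-value is the hypergeometric upper tail $P(X \ge k)$, BH
adjustment across tested terms, and the reported statistics are GeneRatio
$k/n$, BgRatio $K/N$, RichFactor $k/K$, FoldEnrichment $(k/n)/(K/N)$ and the
finite-population z-score

$$z = \frac{k - nK/N}{\sqrt{n \tfrac{K}{N}(1-\tfrac{K}{N})\tfrac{N-n}{N-1}}},$$

validated against two independently printed table rows before freezing. The
q-value column equals the BH-adjusted value: the separate smoothing-based
q-value estimator of the reference enrichment tool is not reproduced, a
documented divergence (published q-values are therefore approximated and
never asserted). Default reporting keeps adjusted p < 0.05 and q < 0.2;
passing both cutoffs as 1 keeps every tested term. Symbol-to-identifier
conversion is an identity mapping — real organism annotation databases are
out of scope.

## Unsupervised views

The volcano plot shows every probe (logFC vs −log10 adjusted p), a dashed
line at −log10(0.05) ≈ 1.301, and intentionally no vertical logFC cutoffs;
adjusted p-values are clipped at 1e-300 before the log so ordinates stay
finite. For the heatmap and ordination, up to 10,000 significant CpGs are
sampled under a fixed seed, rows are standardised to Z-scores with the n−1
sample standard deviation (the usual choice; the source convention is
unstated), and both probes and samples are clustered with Euclidean distance
and complete linkage. Missing values are mean-imputed per probe row *only*
for distance/PCA computation, never for the statistics. PCA of the
sample-by-probe matrix uses centring only — rows are already Z-scored, so
rescaling would be redundant — and reports per-component variance fractions.
Group colours are fixed: blue Control, red Periodontitis.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every end-to-end claim in the test suite is evaluated.

* **Design**: 34 Control and 31 Periodontitis samples in 3 dataset blocks
  (split as evenly as the counts allow), mirroring the integrated cohort the
  package targets. Dataset blocks carry no batch effect by default — the
  emulated analysis applied no batch correction — but `batch_shift_m` exists
  for robustness experiments.
* **Baseline betas**: per-probe means drawn on the M scale from a
  three-component mixture (modes near β = 0.15, 0.85, and 0.5 with weights
  0.45/0.35/0.20, M-scale spread 0.8), mirroring empirical 450K bimodality
  while keeping mass near the boundary so crossings are attainable.
* **Planted effects**: 30% of probes carry a group shift of 2 on the M scale
  (5% crossing upward, 5% downward, the rest shifted away from the boundary
  so their state is preserved). Crossing probes draw the control mean
  uniformly within (0.15, 0.85) of the effect size from the boundary, so both
  true group means keep a margin from 0.5 and state recovery from 30-sample
  group means is reliable without being trivial. Within-group noise is
  Gaussian with sd 1 on the M scale — noise on the modelling scale, matching
  the model's assumptions by construction.
* **Missingness**: element-wise at rate 0.02, plus 1% of probes engineered to
  exceed the 80% filter (exactly ⌊0.8·n⌋+1 missing entries, so removal is
  deterministic).
* **Annotation**: island-relation frequencies default to a typical
  significant-CpG profile (19.86 / 12.60 / 9.80 / 5.20 / 4.77 / 47.77% for
  Island through OpenSea). The gene pool is sized at ~⅔ of the probe count so
  genes average ~1.6 probes: many-to-many structure in both directions
  (probes with 0–3 genes, genes owning several probes) while keeping the
  planted/background contrast detectable at gene level — with too few genes,
  nearly every gene touches a planted probe and enrichment signal washes
  out. Gene symbols are synthetic tokens (`G000001`…); RefSeq ids mirror
  them. No probe chemistry, color channels or IDAT structure is simulated.
* **Determinism**: every generator is reproducible from `seed` (manifest,
  matrix and GMT use distinct sub-seeds) without disturbing the caller's RNG
  stream.

The per-group variance and effect-size defaults are chosen for testability —
the emulated study publishes no per-group variance estimates — so passing
tests demonstrate correctness of the machinery under a faithful *structure*
(bimodality, crossings, missingness, multi-mapping, multi-dataset layout),
not distributional fidelity to any real cohort. Real-data properties the
generator does not emulate: probe-type chemistry differences, spatial
autocorrelation along the genome, cell-composition heterogeneity, and batch
effects (unless requested).

## Numerical and design choices

* Boundary clamp $\varepsilon = 10^{-6}$; the logit base is 2.
* The missingness filter removes *strictly more than* the threshold (a probe
  at exactly 80% missing is retained), and is idempotent.
* Probe order after a merge follows the first input matrix; any stable order
  would do, but determinism is part of the contract.
* `estimate_moderation` requires ≥ 2 probes with positive finite variance and
  fails with guidance when all variances are zero.
* Trigamma inversion is Newton iteration with closed-form endpoints for
  extreme arguments (relative tolerance 1e-8).
* Significance (0.05), state boundary (0.5), missingness (0.8), top-gene
  count (20), heatmap sample (10,000), enrichment cutoffs (0.05 / 0.2) are
  all configurable in `pipeline_config()`; defaults are the conventional
  values above and the configuration file (YAML, JSON-compatible subset) and
  call-level overrides share one schema, call-level winning.
* The pipeline is staged over plain-text artifacts (TSV/CSV/GMT) so any stage
  can be rerun and inspected; a run manifest logs config, seed, package
  version and per-artifact line counts. Missing-input errors name the stage
  that produces the input.

## Problem sizes used by the test suite

Simulation-based checks run at desk scale, chosen as the smallest sizes at
which the statistical assertions are stable: null type-I error pools 10
simulations of 20,000 probes at 10+10 samples; moderation-parameter recovery
uses 10 draws of 50,000 variances (d₀ = 4, s₀² = 1, 10 df); planted-direction
recovery pools 20 simulations of 1,000 probes at 30+30; the dendrogram
group-recovery check uses 5 simulations of 2,000 probes at the full 34+31
design; the default end-to-end pipeline run uses 20,000 probes. Published
in-table anchors (ratio statistics, z-scores, the 40 group-mean beta pairs)
are checked exactly.

## Known limitations

* logFC is defined on the M scale throughout. The published top-gene table
  this package's outputs are shaped after prints logFC values that match
  neither the beta-scale difference nor the M-transform of its printed group
  means, so those particular values are treated as non-reproducible without
  the original accession data; only their classification behaviour is
  asserted.
* Storey-style q-values, GO graph semantics, covariate adjustment,
  normalisation beyond the missingness filter, and IDAT/GEO ingestion are
  all out of scope; generic TSV readers make real exported matrices usable.
* The B-statistic's prior-proportion default (0.01) follows framework
  convention and is not calibrated to methylation data; B is reported, not
  acted on.
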