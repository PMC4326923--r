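---
title: "Temporal trajectory analysis of age-structured RNA-seq: models and design choices"
author: "AgeTrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal trajectory analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

AgeTrends analyses bulk RNA-seq sampled cross-sectionally over ordered age
groups — the motivating design is a short-lived vertebrate brain sampled at
5, 12, 20, 27 and 39 weeks with five biological replicates per age. The
pipeline runs: normalization, differential expression over all pairwise
age-group comparisons, fuzzy c-means clustering of standardized temporal
profiles, quadratic U/bell trajectory classification, hypergeometric
gene-set enrichment with kappa term grouping, thresholded Pearson
coexpression networks (overall and per age), and classical MDS of the
samples. A negative-binomial simulator with ground-truth labels is a
first-class module: every statistical claim the package makes about itself
is a recovery or calibration experiment against that generator.

# Data model and normalization

`AgingExperiment` extends `SummarizedExperiment`: an integer `counts`
assay, per-gene transcript lengths, and per-sample `age_weeks`/`replicate`
columns, validated so that every pairwise age comparison has at least two
replicates per side. RPKM is computed self-containedly,

$$\mathrm{RPKM}_{gs} = \frac{10^9\, c_{gs}}{\ell_g \sum_g c_{gs}},$$

with the library size taken as the column total of the matrix at hand, and
`logTransform()` applies $\log_2(\mathrm{RPKM} + 1)$; the pseudocount of 1
keeps zeros at zero. Two consequences matter for interpretation. First,
column-total normalization is compositional: if a large fraction of the
matrix moves with age, flat genes acquire an apparent opposite trend. The
recovery experiments therefore embed effect genes in a composition-stable
background, as a minority gene family sits in a real transcriptome.
Second, on small simulated matrices the column total is a poor estimate of
the generating library size, so the simulator stores its true library
sizes in `colData` and the generator-calibration test uses those.

# Differential expression

A gene is called differentially expressed when, in at least one of the
$\binom{5}{2} = 10$ pairwise age comparisons, it passes *all three* of:

* a negative-binomial Wald test on counts (median-of-ratios size factors;
  method-of-moments common dispersion per gene, floored at $10^{-8}$; the
  Wald statistic on the difference of log group means referred to a $t$
  distribution with $n_A + n_B - 2$ degrees of freedom — a deliberate
  small-sample choice at $n = 5$ per group);
* an exact two-sided Wilcoxon rank-sum test on log2 RPKM (normal
  approximation with midranks, tie and continuity corrections when ties
  occur);
* a permutation test on the absolute log2 fold change, enumerated
  exhaustively over all 252 assignments for the 5 vs 5 design (and hence
  seed-free there).

Benjamini–Hochberg is applied per test per comparison, and no fold-change
cutoff is imposed. The three tests are methodologically independent in
kind — parametric count model, nonparametric rank, resampling — and their
intersection is conservative: on all-flat null simulations (2000 genes)
each test's type-I error sits near nominal (the exact rank-sum test is
*below* nominal, as a discrete test must be: its smallest two-sided
p-values are multiples of $2/252$), while the intersection calls
essentially nothing.

Two calibration caveats are computed, not assumed, by the acceptance
suite. With strong signals present, BH's data-dependent threshold admits
null genes whose data happen to separate completely between two groups —
and a completely separated 5 vs 5 split makes all three statistics extreme
*at once*, because they are computed from the same data. Combined with the
union over 10 comparisons, the genewise false discovery rate of the final
DEG list is therefore not controlled at the per-comparison level (we
measure roughly 20% at 25% prevalence of strong effects), even though
sensitivity is near 1. Users who need strict genewise FDR should treat the
DEG list as a screening set.

# Temporal clustering

Profiles are per-age means of log2 RPKM (5 values), centered to mean 0 and
scaled to variance 1; constant profiles cannot be standardized and are
excluded with a report. Fuzzy c-means minimizes
$J = \sum_{ij} u_{ij}^m \lVert x_j - v_i\rVert^2$ with the classical
alternating updates, fuzzifier $m = 2$, membership-change tolerance
$10^{-6}$, at most 500 iterations, and the best of 20 random starts
(defaults; all exposed). A profile coinciding with a centroid receives
full membership. The implementation is cross-checked in the test suite
against an independent FCM implementation and, at $m \to 1$, against
Lloyd's k-means.

The number of clusters is chosen by a vote of five validity indices:
modified partition coefficient (maximized), normalized partition entropy
(minimized), Xie–Beni (minimized), Fukuyama–Sugeno (minimized) and the
fuzzy silhouette (maximized); ties break toward smaller k. The *raw*
partition coefficient and entropy are monotone in k and, on any data we
tried including nearly noiseless mixtures, vote for the smallest
candidate; the bias-corrected forms (Dave's modification; entropy divided
by $\log k$) are the standard remedy and are what the electorate uses.

One structural limitation is worth stating plainly, because the package's
own acceptance experiments expose it. The simulator's six archetypes do
not map onto six recoverable clusters in standardized-profile space: a
flat gene's standardized profile is pure noise scaled to unit variance —
an isotropic random direction, not a compact cluster — and the u-shape and
rapid-decay prototypes are nearly collinear after standardization. At the
default noise level the vote settles on small k, and even at negligible
noise it saturates at five. Recovering the architecture of *shaped*
profiles is what the method can do; counting a null archetype as a cluster
is not.

Cluster summaries report, per cluster in size order: the mean profile of
its hard members, a 95% envelope ($\pm 1.96\,\mathrm{sd}/\sqrt{n}$),
monotonicity of the *cluster mean* (consecutive differences of a single
sign — the bookkeeping is a property of clusters, not member genes), and
the initial direction. `groupAverageTrajectory()` reports a gene family's
standardized mean trajectory with its per-age standard deviation and the
percent change of unstandardized mean expression between first and last
age.

# U/bell shape analysis

Each gene's log2 RPKM is regressed on age and age² across all 25 samples
(one point per sample, preserving 22 residual degrees of freedom, rather
than 5 per-age means). The quadratic coefficient's two-sided t-test at
$\alpha = 0.05$, uncorrected across genes, decides significance — the
classification is deliberately a per-gene screen, and the null simulation
confirms it flags ≈5% of flat genes. Significant fits are `u` (positive
curvature, trough) or `bell` (negative curvature, peak); the vertex
$-b/(2a)$ estimates the inversion age, flagged when outside the sampled
range. The generator's bell genes use a Gaussian bump rather than a raw
quadratic, so the quadratic fit is deliberately misspecified; the vertex
is nevertheless recovered (median within ±2 weeks of the true 25 weeks in
the acceptance run) because the bump is exactly quadratic in log space.
The fit itself is the closed-form normal-equations solution on a centered
age basis, verified against an SVD pseudoinverse oracle to $10^{-8}$;
numerically perfect fits decide significance by whether the quadratic
coefficient is nonzero at the response's scale.

# Enrichment

Hypergeometric upper-tail tests against the expressed-gene universe (never
the whole annotation), with sets trimmed to the background before the urn
is formed, BH across tested sets, and fold enrichment $(k/n)/(K/N)$. A
from-scratch two-sided Fisher test (probability-mass summation, with a
$1 + 10^{-7}$ relative tolerance for ties in table probabilities, the
same convention as the reference implementation) is provided for parity;
its one-sided upper tail coincides with the hypergeometric p-value.
Enriched terms are grouped by Cohen's kappa between gene-membership
indicator vectors over the background, single-linkage at $\kappa \ge 0.4$
(conventional; exposed), each group represented by its largest-overlap
member. Term lists from two analyses are intersected per category family,
reporting the intersection as a percentage of the second list.

# Coexpression networks

Edges join gene pairs with Pearson $r \ge$ threshold (default 0.95) on
log2 RPKM; positive correlations only, since the target is coregulation,
and the `assay` argument gives literal RPKM-scale correlation when wanted.
Zero-variance genes are excluded and reported; isolated genes are not
nodes. The correlation matrix is computed in tiles so memory stays linear
in the block size, with exact agreement against the naive double loop
asserted in the tests. The hub is the maximum-degree node (ties broken
lexicographically, all ties reported) with its first-neighbor induced
subgraph. Age-stratified networks recompute edges within each age's five
replicates: at $n = 5$ the sample correlation is heavy-tailed
($P(\hat r > 0.95 \mid \rho = 0) \approx 0.007$), so stratum networks are
sparse and noisy; the threshold is intentionally not recalibrated, and the
cross-age comparison reports edge-set Jaccard indices plus per-component
cluster composition.

# Ordination

Classical (Torgerson) MDS — double-centering of squared Euclidean
distances on log2 RPKM and eigendecomposition, via `cmdscale` — with a
deterministic sign convention (first nonzero coordinate of each axis
positive). Per-age centroids are coordinate means; the "confidence circle"
is defined, since no standard definition exists for it, as the 95th
percentile of within-group distances to the centroid; singleton groups are
flagged instead.

# The simulator

`simulateAgingCounts()` draws
$c_{gs} \sim \mathrm{NB}\!\left(\mu = L_s\,\frac{\ell_g}{10^3}\,
\frac{A_g(t_s)}{10^6},\ \mathrm{size} = 10\right)$, so the expected RPKM
of gene $g$ at age $t$ is exactly its archetype mean $A_g(t)$. Six
archetypes cover the canonical aging trajectories: flat (the null),
linear up/down, rapid decay (exponential approach to a lowered asymptote,
rate 0.3/week — rapidly down-regulated but not extinguished), and
Gaussian-bump U/bell shapes with vertex 25 weeks, near median lifespan.
Defaults: baseline 100 RPKM, amplitudes 1 (0.8 for the decay shapes),
library sizes uniform in $[8\times10^5, 1.2\times10^6]$, lengths in
$[500, 5000]$ b, NB size 10 — moderate bulk-RNA-seq overdispersion. One
seeded generator stream drives every draw, giving bitwise reproducibility.
What the generator does *not* emulate: gene–gene correlation beyond shared
archetypes, batch and sex effects, length biases, outlier samples, or
annotation structure — so passing recovery tests demonstrate correctness
of the machinery under the stated model, not robustness to everything real
data do.

`simulateGeneSets()` builds one set per archetype (80% coverage, 5%
contamination) plus uniform random sets as an enrichment null.

# Problem sizes and numerical choices

The test and acceptance experiments use: 2000-gene all-flat null matrices
over 10 seeds for calibration; the default 1200-gene six-archetype design
for clustering, shape and ordination recovery (validity votes run with 10
random starts, label accuracy averaged over 3 seeds); 20 seeds for
planted-hub recovery and 10 for planted two-block recovery. Convergence
tolerances: FCM $10^{-6}$ on memberships; oracle agreements at $10^{-12}$
(enumeration, correlation) and $10^{-8}$ (least squares, MDS). Ties:
smaller k in the vote; lexicographic for hubs; size-then-lexicographic
for components. Degenerate inputs: all-zero genes are dropped and
reported before testing; constant profiles are excluded from
standardization; zero-variance genes are excluded from networks; exact
centroid coincidence gives full membership; zero margins give Fisher
$p = 1$.

# Known limitations

* Genewise FDR of the final DEG list is not controlled by per-comparison
  BH (measured, see above); the intersection design is a screening rule.
* The validity vote cannot count a null (flat) archetype as a cluster and
  merges near-collinear standardized shapes; at realistic noise it chooses
  fewer clusters than the generator has archetypes.
* RPKM's column-total normalization is compositional; strong global trends
  leak into flat genes' apparent trajectories.
* Correlation networks within 5-replicate strata are heavy-tailed
  estimates; interpret stratum hubs and components qualitatively.
* The quadratic shape test assigns every significant curvature a single
  vertex; plateaus and asymmetric trajectories are approximated, not
  modelled.
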