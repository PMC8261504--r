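---
title: "Methods: crosstalk detection, causal inference and co-target ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crosstalk detection, causal inference and co-target ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdeath)
```

This vignette documents the models and procedures behind each pipeline
stage, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic benchmarks do and do not
demonstrate.

## Cohort model and strata

Samples are binned into five ordinal strata — adjacent normal (code 0) and
tumor grades GS6, GS7, GS8 and GS≥9 (codes 1–4). Normals are the reference
throughout: they anchor differential expression, the per-stratum gene
ranking, and the fold changes that become node weights. Tumors graded
below 6 are binned into GS6 with a warning rather than rejected, since no
lower tumor bin exists. Expression is assumed already log2-normalized; the
package does not merge heterogeneous platforms (each input matrix is
treated as one pre-normalized cohort).

## Hallmark gene selection

Per gene we compute a Welch two-sample t-test (tumor vs normal) on log2
values and the Spearman correlation $r$ with the ordinal stratum over all
samples, normals included at code 0. The Welch test was chosen because no
specific test is canonical for this step and it is robust to the unequal
group variances typical of log-intensity data. Spearman is the default
grade correlation because the stratum is ordinal; Pearson is available via
`method = "pearson"`. Constant genes get $r = 0$, $p = 1$ and a flag so
downstream filters treat them conservatively.

Hallmarks satisfy $p < \alpha$ (default 0.05) and $|r| > r_{\min}$
(default 0.5), are ranked by $|r|$ descending with ties broken by $p$
ascending then gene id, and truncated to `top_k` (default 400). The
ranking key is a documented choice: a combined score would also be
defensible, but $|r|$ directly expresses "progression-linked", and every
component is exported so users can re-rank.

## Pathway dynamics

For each tumor stratum, genes are ranked by signal-to-noise versus the
pooled normals: $(\mu_1 - \mu_0) / (s_1 + s_0)$ with each SD floored at
$0.2\,|\mu|$ (absolute floor 0.2 at zero mean), the classic phenotype
metric for log-scale enrichment analysis; a Welch t-statistic is available
via `metric = "t"`. The weighted Kolmogorov–Smirnov running sum increments
by $|s_i|^w / \sum_{\text{hits}} |s|^w$ at set members and decrements by
$1/(N - |S|)$ elsewhere; the enrichment score ES is the signed
maximum-magnitude deviation. When the positive and negative extrema tie in
magnitude to within $10^{-12}$, the earlier position wins — a deterministic
convention that makes results independent of floating-point summation
order.

The null is a **gene-set permutation**: random sets of matched size drawn
from the ranked universe. Sample (phenotype) permutation is statistically
preferable when per-stratum sample counts are large, but the per-stratum
counts here can be small, and set permutation keeps the null exact and
cheap; `n_perm` defaults to 1000. NES divides ES by the mean |null ES| of
matching sign; nominal $p$ is the same-sign tail fraction; FDR $q$ follows
the standard pooled positive/negative NES procedure. Pathways are
pre-filtered by coverage — the fraction of set genes present in the matrix
(default minimum 0.5) — which stands in for the pathway-matching step any
curated database requires against a given platform.

Each pathway's NES trajectory is correlated (Pearson) with the stratum
code over tumor strata only (default): the normals define the ranking
reference, so including them would re-use the reference on both sides. A
rank-trajectory variant (per-stratum NES rank vs grade) is reported
alongside for mode-level summaries.

## Seeded co-expression

Spearman correlation around seed genes with $|r| > 0.5$ and $p < 0.05$
(t-approximation). The $p$ direction is worth a note: a filter keeping
$p > 0.05$ would retain only noise, so the significance filter is applied
in the conventional direction. `seed_edges_only` scope reproduces the
seeded network; `neighborhood_clique` also tests pairs among neighborhood
members and is the default input for the causal stage.

## Causal network

The gene-regulation network is learned by greedy hill-climbing over DAGs
scored by BIC under a linear-Gaussian model on per-gene z-scored data,
with seeded random restarts (default 10) and a parent cap (default 3).
Scoring is covariance-based with per-(child, parent-set) caching, so
restarts and bootstrap refits are cheap; an exact tie in candidate moves
resolves to the first in a fixed enumeration order, making fits
reproducible. Continuous scoring was chosen over discretization because it
preserves the sign information needed for activation/inhibition calls; a
singular covariance (e.g. duplicated signals) is handled by a $10^{-9}$
ridge.

Edge confidence ("belief") is the nonparametric bootstrap recovery
fraction: the structure is refit on resampled cohorts (default B = 100,
with 2 restarts per refit — the consensus over resamples compensates for
the shallower search) and each original edge's belief is the fraction of
refits containing it, direction-sensitively. Edges below `belief_min`
(default 0.3) are pruned. The belief of a path is the product of its edge
beliefs — multiplying per-edge conditional confidences — so path belief is
non-increasing in path length. Edge signs are the signs of the partial
correlation of parent and child given the child's other parents
(equivalently, the local regression coefficient); a numerically zero
partial correlation falls back to the marginal correlation with a flag.

## Crosstalk graph and path search

Causal directions, signs and beliefs are mapped onto the PPI (edges below
`ppi_min`, default 0.4, dropped); causal edges absent from the PPI are
retained, flagged `causal_only`, with the belief standing in for the
interaction score. Node relevance is the min–max normalization of |log2
fold change| over graph nodes rescaled to $(\delta, 1]$
($\delta = 10^{-6}$ floors the relevance of nodes without expression
data), and traversal cost is $-\log(\text{relevance})$: the
strongest-fold-change node costs 0, and a path's total cost is the sum of
its member node costs, endpoints included. The $-\log$ transform makes
total cost the negative log-product of relevances, so the minimum-cost
path is the maximum-relevance route; `cost = 1/relevance` would
overweight single bad nodes. The raw-versus-normalized weighting question
is genuinely open; min–max normalization keeps costs comparable across
cohorts and is the documented default.

The minimum-total-vertex-cost path is found by Dijkstra on the node-split
transform (each node $v$ becomes $v_{in} \to v_{out}$ carrying the node
cost; edges become zero-cost arcs). Ties break by fewer hops, then by
lexicographically earliest node sequence — fully deterministic, which the
brute-force enumeration tests exercise with coarse (frequently tying)
costs. Loopless $k$-shortest paths use Yen's scheme over the same
transform. Causal edge directions are not enforced by default (the
crosstalk route mixes interaction and causal evidence); with
`respect_direction = TRUE`, causal edges become one-way while interaction
edges stay traversable both ways.

## Co-target ranking

Candidate pairs are unordered pairs of hallmark genes present in the
graph, both upregulated and positively grade-correlated by default
(co-targets are genes to inhibit). The composite score is
$0.4\,\text{rn}(\text{mean } |r|) + 0.4\,\text{rn}(-\text{path cost}) +
0.2\,[\text{both druggable}]$, where $\text{rn}$ rank-normalizes each
component to $[0, 1]$ — so the ranking is invariant to monotone transforms
of the raw components and transparent to re-weighting. Druggability is a
user-supplied gene list, not an embedded database. Disconnected pairs are
dropped and logged. The weights are a documented default, not a fitted
quantity; all components are exported.

## Methylation links

Per gene, a Mann–Whitney test on promoter beta values (tumor vs normal,
BH-adjusted) with an effect-size gate: hypermethylated requires
$\Delta\beta > 0.1$ and $q < 0.05$, hypomethylated the mirror image —
significance without effect is called unchanged. The Mann–Whitney choice
suits bounded beta values. Methylation–expression coupling is Spearman
over shared samples (≥ 10 required per gene). Probe-level aggregation to
gene-level promoter beta is upstream of this package.

## The synthetic generator, and what the benchmarks show

`simulate_cohort()` generates five strata (default 60 samples each, 200
genes). Trend genes follow
$\mu_g + \beta_g \cdot \text{stratum} + \text{block} + \varepsilon$, with
$\beta_g$ calibrated through the bivariate-normal relation
$\rho = 2 \sin(\pi r_s / 6)$ so the realized Spearman $|r|$ lands near the
configured `trend_strength` (the ordinal stratum makes this approximate;
the calibration test bounds the error at ±0.1). Co-expression blocks share
a latent factor with within-block correlation `block_rho`. The planted
chain is generated sequentially as a linear-Gaussian structural model
(`downstream = sign·coef·upstream + noise`, residuals scaled to preserve
variance), its source being a positive-trend gene, so the chain endpoints
are two upregulated seeds; this matches the causal stage's model class,
making parameter recovery a well-posed test. Pathways spread over the
twelve cell-death modes, with "progressing" modes drawing mostly from
trend genes; the PPI contains every chain edge (score ≥ 0.7) plus
Erdős–Rényi decoys; methylation for trend and chain genes follows
$\text{logistic}(-k \cdot z(\text{expression})) + \text{noise}$.

Two generator choices define the co-target benchmark
(`cotarget_benchmark_config()`): background trend genes carry 70% of the
chain source's trend strength — the planted seeds are the cohort's
strongest progression genes, which is precisely the situation the ranking
is meant to detect — and decoy PPI edges never connect two chain genes, so
the planted crosstalk is genuinely indirect and only consecutive chain
edges are real interactions. The benchmark marks the two seeds plus six
background trend genes druggable, emulating the drug-target annotation a
user supplies. These are statements about the scenario, decided with the
scenario: recovering a pair that is *not* distinguished from the
background is not a well-posed benchmark.

What passing these benchmarks shows: the statistics agree with
brute-force oracles; the selection, learning and search stages recover
planted structure at realistic noise. What it does not show: performance
on real cohorts with batch effects, platform mixtures, non-monotone
trends, or hub-dominated scale-free PPIs — none of which the generator
emulates. The defaults (200 genes, 60 samples per stratum, 10-node causal
benchmarks at $n = 500$, B = 25 bootstrap resamples and 15 causal-network
genes in the end-to-end scenario) are the package's reference problem
sizes, chosen so the complete validation suite runs comfortably on a
laptop while leaving each stage's signal-to-noise regime nontrivial.

## Degenerate inputs and numerical conventions

Zero-variance genes: flagged, $r = 0$, $p = 1$, skipped in co-expression.
Zero pooled variance in the Welch test: $p = 1$ at equal means, $p = 0$
otherwise. Gene sets covering none or all of the universe: skipped with a
warning. All fold changes equal: every node cost 0 with a warning.
Disconnected seed pairs: empty result with `"disconnected"` status.
Duplicate expression rows collapse to the max-variance row; genes with
more than 20% missing values are dropped, the rest median-imputed. All
randomness flows from one global seed via per-stage derived seeds
(`seed·1000 + stage index`), and every stochastic routine is reproducible
given its seed.

## Known limitations

The causal stage assumes linear-Gaussian local models and recovers
skeletons reliably but orientations only partially (Markov-equivalence
limits apply); beliefs quantify resampling stability, not posterior
probability. Gene identifiers are reconciled by uppercasing only — no
alias mapping. The enrichment null permutes gene sets, not phenotypes.
Genome-wide all-pairs co-expression is deliberately out of scope
(quadratic cost); the seeded scopes cover the pipeline's needs.
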