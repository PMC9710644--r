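---
title: "Hierarchical dissimilarity for functional beta-diversity: model, design choices and limits"
author: "hmsdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical dissimilarity for functional beta-diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmsdiv)
```

## The problem

A functional profile represents a microbial community as relative
abundances of gene families (KEGG Orthologs, KOs). Flat dissimilarity
metrics — Bray–Curtis, Cosine, Euclidean, Jensen–Shannon — compare two
profiles coordinate by coordinate, so all similarity evidence must come
from *shared* gene families. KO profiles, however, are high-dimensional
and sparse: communities from different habitats often share few KOs even
when they run largely the same metabolism through non-orthologous
enzymes. A flat metric then saturates near its maximum and the
beta-diversity pattern it induces is wrong in two characteristic ways,
both of which this package's synthetic designs reproduce (see below).

Gene families are not unrelated coordinates: each KO is annotated to one
or more level-3 metabolic pathways, each level-3 pathway to level-2
parents, each level-2 to level-1 categories (the KEGG BRITE three-level
classification). Unlike taxa, which hang on a phylogenetic *tree*, a
single gene family routinely serves several pathways, so the annotation
is a many-to-many layered graph, not a tree. The package therefore never
assumes single parentage at any link.

## The dissimilarity

Let `x`, `y` be KO relative-abundance vectors. *Collapsing* to level 3
adds each KO's abundance to every level-3 pathway it annotates; the
procedure iterates upward (level-2 values are sums of their level-3
children, and so on). Collapsed vectors are deliberately **not**
renormalized: upper levels are linear combinations of lower levels, a KO
feeding several pathways is counted once per pathway, and the general
Bray–Curtis form `Σ|x−y| / Σ(x+y)` is well defined for any non-negative
totals. The dissimilarity is

$$\mathrm{Dist}(x,y) \;=\; \frac{\sum_{i\in\{0,3,2,1\}} W_i\,
\mathrm{Dist}_i(x,y)}{\sum_i W_i},$$

with `Dist_0` the Bray–Curtis distance on the KO vectors and `Dist_i`
the Bray–Curtis distance on the level-`i` collapsed vectors.

Parameters that matter:

* **Weights** (`hmsWeights()`): `W0 = 4` for the KO level, `W_i = i` for
  pathway level `i`. The KO level carries the most resolution and gets
  the largest weight; deeper (more specific) pathway levels are weighted
  above shallower ones. Weights are dimensionless, configurable per call
  and never global state. `w1 = w2 = w3 = 0` recovers plain Bray–Curtis
  exactly, which the tests assert.
* **Normalization**: profiles are always normalized to relative
  abundance before distance computation (`normalizeProfiles()` is
  idempotent, so already-normalized input is unaffected). All-zero
  samples are left as zeros, flagged and warned about once.
* **Coverage**: KOs absent from the hierarchy still participate fully in
  `Dist_0` but contribute nothing at pathway levels; a single summary
  warning per run lists them.

Useful consequences, all property-tested: the value lies in `[0, 1]`,
is symmetric, is zero on identical profiles, is bounded by the smallest
and largest per-level distance (it is a weighted mean), and is invariant
to identically permuting the feature order of both inputs. The triangle
inequality is *not* guaranteed — Bray–Curtis itself does not satisfy it —
so downstream methods must not assume metricity; the PCoA handles the
resulting negative eigenvalues explicitly.

## Degenerate inputs and numerical choices

* Two vectors that are all-zero at some level get distance 0 at that
  level (they are indistinguishable there; this avoids 0/0).
* Cosine distance on a zero vector is an error rather than a sentinel:
  a direction-free sample should be filtered upstream, silently scoring
  it would bias group means.
* Jensen–Shannon divergence uses the natural logarithm (the divergence
  itself, not its square root), renormalizes its inputs, and applies the
  `0·log 0 = 0` convention term by term.
* All per-pair summations run in a fixed feature-index order in double
  precision. Pairs of the distance matrix are enumerated statically in
  row-major upper-triangle order and computed independently — there is no
  cross-pair accumulation — so the matrix is bit-identical for any
  `workers` value; parallelism is purely a wall-time concern. The tests
  assert bit-identity against a per-pair brute-force loop.

## PCoA

`pcoa()` is classical (metric) MDS by Gower double centering:
`B = −½·J·D²·J` with `J = I − 11ᵀ/n`, eigendecomposition of `B`, and
coordinates `v_j · √λ_j` for the top-`k` positive eigenvalues. Choices:

* **Negative eigenvalues** (routine for Bray–Curtis-derived matrices)
  are discarded and counted in `nNegative`; no Lingoes/Cailliez
  correction is applied. This is the plainest classical-MDS reading and
  keeps coordinates comparable with `stats::cmdscale`, which the tests
  use as an independent oracle (agreement to 1e−6 required).
* **Explained variance** is reported relative to the positive-eigenvalue
  total only, so the proportions are interpretable as shares of the
  representable variation.
* **Sign convention**: eigenvector signs are arbitrary, so each axis is
  flipped to make its largest-magnitude loading positive (ties broken by
  the lowest sample index). Coordinates are thus reproducible across
  runs and platforms.
* `k` defaults to 3 (ordination plots use 2 or 3 axes); `k ≥ n` is an
  error, and if fewer than `k` positive eigenvalues exist the result is
  truncated with a warning rather than padded.

`procrustesTest()` is the symmetric Procrustes comparison: both
configurations are column-centered and scaled to unit total sum of
squares, the correlation is the sum of singular values of `AᵀB` (1
exactly for shapes identical up to translation, rotation and uniform
scaling), and the Monte-Carlo p-value permutes the row order of `B` with
the `(1 + exceedances)/(1 + permutations)` estimator, so p can never be
0.

## ANOSIM

`anosimTest()` ranks all `n(n−1)/2` distances (average ranks for ties —
the standard convention) and computes
`R = (r̄_between − r̄_within)/(M/2)`, `M = n(n−1)/2`. Being rank-based, R
is invariant under any order-preserving transform of the distances,
which the tests assert along with agreement with `vegan::anosim`. The
permutation p-value uses the same add-one estimator as the Procrustes
test; the default 999 permutations resolves p down to 0.001, enough to
call significance at the conventional 0.01 level.

## The synthetic benchmark designs

The generators exist so that every behavioural claim about the metrics
is testable without external data. Exact published compositions for
such designs are not available, so the generators parameterize the
documented group structure with fixed defaults; all randomness flows
from the single `seed` of `syntheticDesign()`.

**Convergent-pathways design** (`simulateConvergentPathways()`). Three
groups of 10 samples over 12 KOs and 8 level-3 pathways in two branches.
Group m1 shares 2 KOs with m2 but only 1 with m3; yet m1's and m3's KOs
collapse onto exactly the same five level-3 pathways with matched base
abundances (0.2 each), while m1 and m2 share only 2 of 5 level-3
pathways and diverge at levels 2 and 1. KO overlap and pathway identity
therefore point in opposite directions: flat metrics rank
`dist(m1,m2) < dist(m1,m3)`, the hierarchical metric the reverse — the
metabolically correct reading. With the default weights the base
compositions give `Dist(m1,m3) ≈ 0.32` (only `Dist_0` is non-zero)
versus `Dist(m1,m2) ≈ 0.6` (all levels disagree), so the ordering is
robust to the within-group noise.

**Sparse zero-inflated design** (`simulateSparseProfiles()`). Groups m1
and m2 draw from 60-KO pools sharing 8 KOs, both pools annotating the
same pathway branch; m3 occupies a disjoint pool on a separate branch.
Every cell is zeroed independently with probability `sparsity` (default
0.6) before renormalization; a sample left all-zero is redrawn, at most
100 times. Group m3 is the extreme case: its pool is partitioned into
disjoint 6-KO blocks, one per sample, so within-m3 supports never
overlap. Flat overlap-counting metrics then saturate exactly (every
within-m3 Bray–Curtis distance is 1.0, cosine 1.0, JSD log 2): the group
collapses to a single point and its internal beta-diversity is erased.
The hierarchical metric still resolves within-m3 variation because the
blocks share the pathway branch — its within-m3 coefficient of variation
stays around 0.1–0.2. Between groups, the 8 shared m1/m2 pool KOs keep
`dist(m1,m2) < dist(m1,m3) = 1` for every metric, so the designs
disagree only where they should.

**Within-group noise** in both designs is an independent multiplicative
perturbation `value × (1 + u)`, `u ~ Uniform(−noise, +noise)`, default
`noise = 0.1`, then renormalization — subtle abundance variation around
a shared group composition, the simplest model with bounded relative
error and no sign problems.

What the generators do *not* emulate: realistic KO richness (thousands
of features), compositional correlation structure between pathways,
sequencing-depth-dependent zero inflation, or overdispersed counts.
Passing tests on these designs demonstrate the *ordering and spread*
properties of the metrics under controlled structure, not performance
on any particular real habitat.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
designs' native size (30 samples, up to ~180 features), PCoA oracle
comparisons up to n = 50, 10 000 Procrustes permutations and 999 ANOSIM
permutations — sizes chosen so the entire suite completes in seconds
while still exercising every code path at the scale the designs define.
Every stochastic step (generators, permutation tests) takes an explicit
seed; nothing reads global entropy.

## Known limitations

* The dissimilarity is not a metric (no triangle inequality), so
  methods requiring metricity (e.g. some clustering index bounds) need
  care.
* Only the three-level hierarchy depth is supported; deeper or
  alternative annotations (COG, MetaCyc) would need a generalized
  collapse step.
* Distance matrices are held dense in memory; the implementation
  targets desk-scale studies (hundreds to a few thousand samples), not
  the 10⁴–10⁵-sample regime.
* Serialized distance matrices round to six decimals; workflows needing
  bit-exact round trips should keep objects in memory.
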