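---
title: "Multi-scale structure-function fusion: models, parameters and design choices"
author: "gammaSFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale structure-function fusion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaSFC)
```

# The model

Structural connectivity (SC) and functional connectivity (FC) are two views
of the same brain network: streamline counts from diffusion tractography,
and Pearson correlations between regional fMRI time series. Their agreement
is strongest at the level of network modules, and the scale at which that
agreement peaks is an empirical question. `gammaSFC` treats both the
structure-function mixture and the module scale as free parameters and
optimizes them jointly.

The pipeline is:

1. **Population aggregation.** Per-subject matrices are reduced to one
   population matrix per modality by the link-wise median across subjects.
   Zeros (absent streamlines) participate in the median like any other
   value, so a link must be present in at least half the cohort to survive
   in a count matrix.
2. **Density matching and binarization.** SC is binarized at zero. FC is
   thresholded to the same number of links K (keeping its K strongest
   positive correlations) and binarized, so that the two binary graphs are
   comparable in density.
3. **Fusion.** `fuseConnectivity()` computes
   $\gamma SFC = \gamma\,FC_p + (1-\gamma)\,SC_p$ elementwise over the
   binary pair. Off-diagonal entries therefore take only the values
   $\{0, \gamma, 1-\gamma, 1\}$, and the endpoints recover each modality
   exactly.
4. **Hierarchy.** The fused matrix is clustered by weighted-average
   (WPGMA) agglomeration under correlation distance
   $d(i,j) = 1 - r(\text{row}_i, \text{row}_j)$ between connectivity
   profiles. WPGMA heights are monotone, so cutting the dendrogram at
   cardinality $M$ gives a nested family of partitions.
5. **Cross-modularity.** Each cut partition is scored by
   $\chi = (Q_F \cdot Q_S \cdot T_{FS})^{1/3}$, where $Q_F$ and $Q_S$ are
   Newman–Girvan modularities of the binary FC and SC graphs under the
   *shared* fused-tree partition and $T_{FS}$ is the mean DICE overlap of
   intra-module link sets. `optimizeCrossModularity()` searches the
   $(\gamma, M)$ plane and returns the maximizing cell.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gammas` | 0, 0.1, …, 1 | fusion mixtures searched; the 11-point grid is the coarsest that resolves a one-decimal optimum |
| `mRange` | 2–120 | cut cardinalities searched; the upper bound is where $\chi$ typically peaks well below, and it is clipped to N |
| `minModuleSize` | 3 | modules with 1–2 nodes carry no internal community structure and are counted as invalid at the optimum |
| `fcRule` | `"positive"` | FC links ranked by value; `"absolute"` ranks by magnitude for workflows that treat anti-correlations as connectivity |
| `tfsStrategy` | `"link-dice"` | see below |
| `zThreshold` | 2 | disorder gene-set flags at |z| > 2 |

# Design choices where the design was open

**$T_{FS}$ under a shared partition.** The similarity term is defined as a
DICE coefficient between functional and structural modules averaged over
modules. With a single partition applied to both graphs, a node-set DICE is
trivially 1, so the default `"link-dice"` strategy compares what remains
informative: for each module, the DICE overlap between its intra-module
link sets in FC and in SC (modules with no intra links in either graph are
excluded from the mean). The legacy `"node-dice"` strategy — cluster FC and
SC separately, cut both at $M$, and average each functional module's best
node-set DICE over structural modules — is retained for comparability with
earlier module-matching work; note it does not depend on $\gamma$.

**FC thresholding sign.** Whether the density-matching threshold ranks
correlations by value or by magnitude is a modeling choice; ranking
positive correlations by value is the conservative convention for binary
FC graphs and is the default, with `"absolute"` exposed as an option.
Ties exactly at the K-th value are all kept (deterministic, no arbitrary
index-order tie-breaking); the resulting surplus is reported in the
`PopulationPair`.

**Correlation distance over full rows.** Connectivity profiles enter the
distance with all N columns, diagonal fixed at 0 (the simplest reproducible
convention); `excludeSelf = TRUE` removes the mutual columns of each pair
instead, for sensitivity analyses.

**"Weighted" linkage.** Agglomeration uses WPGMA (`stats::hclust` method
`"mcquitty"`), the standard meaning of weighted linkage in agglomerative
clustering software; the merge order and heights are cross-checked in the
test suite against an independent $O(N^3)$ agglomerator.

**Tree-metric conventions.** Height H of a leaf is counted from the top of
the tree: the cut cardinality (M = 1 being the root) at which the leaf
first stands alone. MH averages H over a module's members. The multi-scale
index of a module counts the consecutive cut cardinalities across which
its leaf set stays intact, from the level at which it is merged into its
parent down to the level at which it first appears as its own cluster; on
the worked chain tree over $\{a,b,c,d\}$ this gives MSI$(\{a,b\}) = 2$
(intact at cardinalities 3 and 2). Cuts are taken by merge count rather
than by height, so tied merge heights cannot produce ill-defined
partitions. Singleton modules have undefined (NA) segregation rather than
0, to avoid spurious entries in metric correlations.

**z-scores.** Disorder scores use the sample standard deviation (n − 1)
across modules. Gene matching is case-insensitive exact symbol match; alias
resolution would require an external database and is out of scope. Group
scores pool the union of member-disorder symbols, so a gene shared by two
disorders in a group counts once. The Methods-style mean summary is the
default; a median summary is available via `stat = "median"`.

# The synthetic cohort generator

`syntheticSpec()` / `generateCohort()` emulate the statistical structure
the pipeline assumes: a modular skeleton shared between modalities, with
modality-specific noise.

* SC subjects are planted-partition Bernoulli graphs (within-module link
  probability `pIn` = 0.8, between `pOut` = 0.05 by default) derived from
  one population base graph by per-subject link flips
  (`subjectFlipProb` = 0.05).
* FC subjects are block correlation matrices (`fcMuIn` = 0.6,
  `fcMuOut` = 0.05) with population-level (`fcNoiseSd` = 0.1) and
  subject-level (`subjectNoiseSd` = 0.1) Gaussian noise, clipped to
  [−1, 1]. FC is generated directly as a noisy block matrix rather than
  via simulated BOLD time series: the pipeline consumes correlation
  matrices, and a time-series generative model would add parameters
  without adding test power.
* The default cohort is 60 nodes in 4 equal modules, 20 subjects — large
  enough that density matching, fusion, clustering and the $(\gamma, M)$
  search all operate away from degenerate regimes, small enough that the
  full search runs in seconds.
* Optional nested sub-modules tighten within-sub-block parameters (midway
  between the level-1 value and 1 by default), producing a genuinely
  multi-scale planted hierarchy.
* Expression data are iid Normal(0, 1) over samples × genes with disjoint
  random gene sets; planted (module, set, effect) triples shift a set's
  genes in one module's samples by `effect` noise-sd.

What passing tests on these fixtures do **not** show about real data: real
SC densities are distance-dependent and heavy-tailed rather than uniform
Bernoulli; real FC matrices are positive-semidefinite with global
signal structure, whereas clipped block-plus-noise matrices need not be;
module sizes in real cortex are heterogeneous; and gene expression has
strong spatial autocorrelation that the iid baseline lacks. The fixtures
validate the algorithmic contract — recovery of planted structure and
calibration under a known null — not neurobiological realism.

# Numerical choices and degenerate inputs

* Asymmetries up to 1e−8 are averaged away on load; anything larger is an
  error (it usually means misaligned node orders), never silently fixed.
* Diagonals are stored and treated as zero everywhere.
* A constant connectivity row (e.g. an isolated node) makes correlation
  distance undefined and raises an error naming the node, rather than
  propagating NaN distances.
* $\chi$ is recorded as NA wherever any factor is negative, and NA cells
  are excluded from maximization; grid ties are broken toward smaller M,
  then smaller $\gamma$ (parsimony, determinism).
* Merge ties inside `hclust` are resolved by its internal order; with
  continuous-valued fused matrices exact ties occur only in deliberately
  degenerate fixtures.

# Validation problem sizes

The test suite validates each statistic against independent brute-force
oracles on ≥ 50 random instances with N ≤ 12 at tolerance 1e−10, the WPGMA
path against an $O(N^3)$ reference agglomerator, end-to-end parameter
recovery on the 60-node cohort above (expecting M* = 4 and adjusted Rand
index ≥ 0.95 against ground truth for every $\gamma$ in the default grid),
and the disorder-flag rate under a null (zero effect) against the exact
finite-M law for within-sample z-scores: with M modules,
$z^2 M/(M-1)^2 \sim \mathrm{Beta}(1/2, (M-2)/2)$, whose |z| > 2 tail at
M = 26 is 0.0386 (the Normal mass 0.0455 is only the M → ∞ limit). The
calibration check uses 200 seeded replicates (52,000 module–disorder
pairs) and a 3-binomial-sd band; a 10-noise-sd planted effect must be
flagged in every replicate.

# Known limitations

* The package consumes region-by-region matrices; it does no image
  processing, tractography, parcellation, or expression preprocessing.
* Partitions come only from tree cuts, as the method prescribes — there is
  no Louvain/Leiden path.
* Only binarized fusion is implemented; weighted fusion of raw matrices is
  a different model with different invariants.
* Atlas overlap is computed at the resolution of the supplied elements;
  voxel-accurate overlap requires per-element weights (e.g. voxel counts),
  which the interface accepts but does not derive.
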