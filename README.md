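# gammaSFC

Multi-scale fusion of structural and functional brain connectivity.

## The problem

Structural connectivity (SC, streamline counts from diffusion tractography)
and functional connectivity (FC, Pearson correlations between regional fMRI
time series) describe the same brain with only partial agreement, and their
correspondence is strongest not at the level of individual links but at the
level of network *modules* — and at no single privileged spatial scale.
`gammaSFC` is for network neuroscientists who have region-by-region SC and
FC matrices (at any parcellation resolution) and want to ask: at what
mixture of structure and function, and at what number of modules, is the
modular organization of the two modalities most consistent?

## The method

Per-subject matrices are aggregated into population matrices by taking the
link-wise **median** across subjects. The sparse SC population matrix is
binarized at zero; the FC matrix is thresholded to the same link density
(keeping its K strongest positive correlations, K = SC link count) and
binarized. The two binary matrices are fused through a single parameter:

    γSFC = γ · FC_p + (1 − γ) · SC_p,   γ ∈ [0, 1]

so γ = 0 is pure structure, γ = 1 pure function, and intermediate γ weights
links by the modality carrying them (1 for links in both, γ for FC-only,
1 − γ for SC-only).

For each γ, the fused matrix is clustered by weighted-average (WPGMA)
agglomeration under correlation distance between connectivity profiles,
giving a dendrogram whose cut at cardinality M yields a nested family of
partitions. Each partition is scored by **cross-modularity**

    χ = (Q_F · Q_S · T_FS)^(1/3)

where Q_F and Q_S are the Newman–Girvan modularities of the binary FC and
SC graphs under that shared partition, and T_FS is the mean DICE overlap of
intra-module link sets between the two modalities. The pipeline searches
the (γ, M) plane and returns the maximizing cell, excluding modules of
fewer than 3 regions from the valid-module count.

Around this core the package provides multi-scale dendrogram metrics
(module size MS, multi-scale index MSI, height H, module height MH), node
strength and module segregation summaries, overlap annotation of a
partition against reference atlas labelings (e.g. Desikan–Killiany regions
or resting-state networks), z-score scoring of modules against disorder
gene-set panels, and a seeded synthetic cohort generator with planted
nested modules used throughout the test suite.

## Worked example

```r
library(gammaSFC)

spec <- syntheticSpec(seed = 42)          # 60 nodes, 4 planted modules of 15
cohort <- generateCohort(spec)
pair <- matchDensityAndBinarize(
  populationMedian(lapply(cohort$subjects, `[[`, "sc")),
  populationMedian(lapply(cohort$subjects, `[[`, "fc")))
pair
#> population SC/FC pair: 60 nodes, 390 links (density 0.2203, 0 threshold ties kept)

grid <- optimizeCrossModularity(pair, mRange = 2:15)
grid
#> cross-modularity grid: 11 gammas x 14 module counts; optimum chi = 0.7284
#> at gamma = 0, M = 4 (4 modules with >= 3 nodes)

partitionAgreement(optimum(grid)$partition, cohort$truth)
#> [1] 1

tree <- buildMergeTree(fuseConnectivity(pair, optimum(grid)$gamma))
treeMetrics(tree, 4)$modules
#>   module MS MSI       MH
#> 1     M1 15   4 34.40000
#> 2     M2 15   6 40.33333
#> 3     M3 15   2 37.86667
#> 4     M4 15  15 48.06667
```

The density-matched pair keeps 390 of 1770 possible links in each modality.
The search finds its maximum cross-modularity (χ = 0.73) at the planted
scale M = 4, and the recovered partition matches the planted one exactly
(adjusted Rand index 1). The tree metrics read: every module holds 15
regions (MS); M4 stays intact across 15 consecutive cut levels before
splitting (MSI); its member regions separate into singletons only around
cut level 48 of 60 on average (MH).

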