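# phylospat

Spatial phylogenetics of gridded species assemblages: from point
occurrence records and a dated (or datable) phylogeny to per-grid-cell
measures of evolutionary diversity, endemism, and phylogenetic community
structure. The package is aimed at biogeographers and community
phylogeneticists running continental- or regional-scale analyses of
herbarium/museum occurrence data — and at anyone who needs those analyses
to be testable, since it ships a synthetic-landscape generator that
reproduces the statistical structure the methods assume.

## What it computes

For each cell of an equal-area grid holding a species presence set:

- **Species richness** S.
- **Phylogenetic diversity** (Faith),
  `PD = Σ L(b)` over the branches `b` of the minimal subtree spanning the
  cell's species (root path included by default).
- **Phylogenetic endemism** (Rosauer),
  `PE = Σ L(b) / R(b)`, where `R(b)` is the number of cells containing at
  least one descendant of branch `b`. PE concentrates where much
  evolutionary history is geographically restricted; summed over cells it
  conserves the total tree length.
- **Weighted endemism**, `WE = Σ_s 1 / range(s)` — the species-level
  analogue of PE.
- **Phylogenetic structure**: mean pairwise distance (MPD) and mean
  nearest-taxon distance (MNTD) among the cell's species, standardized
  against richness-preserving null draws from a continental or regional
  species pool into the Net Relatedness Index
  `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)` and the Nearest Taxon
  Index (NTI, same form on MNTD). Positive values: co-occurring species
  more related than chance (phylogenetic clustering, e.g. environmental
  filtering); negative: less related (evenness, e.g. refugial mixtures of
  distant lineages). Null draws never re-use a species combination, and
  each (pool, richness) class stops at a maximum iteration count (default
  4999), on convergence, or when all C(N, S) combinations are exhausted —
  in which case the null is the exact complete enumeration.
- **Sorensen dissimilarity** between regional floras, for checking a
  regionalization.

Supporting tools: supertree assembly by taxonomic grafting (species
attached under their genus or family node, assuming genus monophyly) and
bladj-style ultrametric dating by even-spacing interpolation between
landmark node ages.

## Worked example

Simulate an environmental-filtering landscape (niche-conserved species
sorted along two orthogonal gradients), grid it, and score phylogenetic
structure against the continental pool:

```r
library(phylospat)

cfg <- scenario_config("filtering", n_species = 60,
                       n_cells_x = 8, n_cells_y = 8, seed = 42)
sim <- simulate_scenario(cfg)
grid <- filter_min_richness(sim$grid, 5L)   # keep cells with > 5 species

res <- run_nri_analysis(grid, sim$tree, pool_kind = "continental",
                        config = null_config(max_iter = 999), seed = 42)
head(res$cell_metrics[, c("cell_i", "cell_j", "region", "S", "PD", "PE",
                          "WE", "MPD", "NRI", "class")], 5)
#>   cell_i cell_j region  S    PD    PE     WE    MPD   NRI         class
#> 1      0      1   west  8 285.7 24.49 0.9262  93.36 6.099 clustered_sig
#> 2      0      2   west  9 309.0 28.38 1.0929  93.75 6.700 clustered_sig
#> 3      0      3   west 10 381.5 32.41 1.1838 103.99 6.198 clustered_sig
#> 4      1      0   west  7 302.6 20.48 0.8282 124.63 3.121 clustered_sig
#> 5      1      1   west 18 637.6 49.48 2.0322 133.43 5.167 clustered_sig
```

Reading the first row: the cell at grid index (0, 1) holds 8 species whose
minimal spanning subtree totals 285.7 Myr of branch length (PD), of which
24.5 Myr is its "ownership" share after dividing each branch by its cell
range (PE). Its observed MPD of 93.4 Myr sits 6.1 null standard deviations
*below* the mean of 999 richness-8 draws from the full species pool
(NRI = +6.1): its species are far more closely related than a random
assemblage, significant phylogenetic clustering — exactly what a
niche-conserved filtering landscape should produce. Half the retained
cells (16/32) are significantly clustered; the median NRI across cells is
+1.71. The null audit records how each distribution ended:

```r
head(subset(res$null_audit, metric == "MPD"), 3)
#>          pool S n_draws null_mean null_sd    stop_reason
#> 1 continental 6     999     167.3   15.88 max_iterations
#> 3 continental 7     999     166.9   13.54 max_iterations
#> 5 continental 8     999     167.3   12.13 max_iterations
```

Real data enter through the same surfaces: `read_occurrences()` +
`grid_occurrences()` + `aggregate_cells()` for records in a projected CRS,
`read_newick()` / `graft_species()` / `bladj_date()` for the tree, and
`restrict_to_species()` for growth-form subsets. A thin command-line
wrapper over these functions is installed at `inst/cli/phylospat.R`
(subcommands `simulate`, `grid`, `date`, `graft`, `metrics`, `nri`,
`sorensen`); see `?phylospat_cli`.

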