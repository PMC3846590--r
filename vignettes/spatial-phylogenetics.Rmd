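---
title: "Spatial phylogenetics of gridded assemblages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phylogenetics of gridded assemblages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phylospat implements a continental-scale spatial-phylogenetics workflow:
point occurrence records are aggregated into grid-cell assemblages, a
supertree is assembled by taxonomic grafting and dated by even-spacing age
interpolation, and each cell is scored for species richness, phylogenetic
diversity (PD), phylogenetic endemism (PE), weighted endemism (WE), and
phylogenetic community structure (MPD/NRI and MNTD/NTI) against
richness-preserving null models drawn from continental or regional species
pools. This vignette records the model choices, parameter meanings, and
numerical conventions; the README shows the workflow itself.

## From points to assemblages

Occurrences must arrive in a projected planar coordinate system in meters;
the package deliberately performs no geographic-to-projected transformation
(that is a pre-processing concern, and grid cells of a stated edge length
presuppose a metric projection). A record at $(x, y)$ falls in cell
$(\lfloor (x - x_0)/w \rfloor, \lfloor (y - y_0)/w \rfloor)$ for cell width
$w$ and origin $(x_0, y_0)$ — cells are half-open on both axes, so boundary
points belong to the higher-indexed cell, and duplicate records collapse to
a single presence (all downstream metrics are presence-based; none of the
analyses weight by abundance). `aggregate_cells()` coarsens a grid by an
integer factor (e.g. 10 km to 50 km cells with factor 5), unioning species
sets; the region label of a coarse cell follows its children by majority,
with ties broken toward the lexicographically smallest label so aggregation
is deterministic. `filter_min_richness()` implements the strict "more than
*n* species" retention rule (default $n = 5$) that keeps sparsely occupied
cells from dominating maps of marginal habitat.

Region membership is a property of cells, not species: a widespread species
contributes to the pool of every region it touches.

## Tree assembly and dating

`graft_species()` enriches a backbone tree whose internal nodes carry genus
and family labels: a species missing from the backbone becomes a new tip
under its genus node if present, otherwise under its family node, otherwise
it is reported unplaced and skipped with a warning. Multiple attachments at
one node form polytomies — the operation assumes genera are monophyletic and
makes no attempt to resolve genera that are not. Grafted edges carry *no*
branch length (absent, not zero): a grafted tree must be dated before any
branch-length-based metric, because approximate ages are more informative
than pretending all branches are equal.

`bladj_date()` assigns ages by even interpolation between landmark ages
supplied for labeled nodes (for empirical work, published crown-group ages
for orders and major clades). The root must carry a landmark; tips are age
0. Landmarks are processed oldest first; each chain of undated nodes
between an already-dated ancestor (age $t_A$) and a dated node below (age
$t_D$) is spaced evenly, the $k$-th of $m$ intervening nodes receiving
$t_A - k\,(t_A - t_D)/(m+1)$. Once dated, a node is never revised, and a
landmark age is never altered; branch lengths are recomputed as age
differences, so the output is exactly ultrametric.

One rule here was genuinely open: when a chain of undated nodes leads to
*several* dated descendants, which one anchors the interpolation? Anchoring
on the nearest (fewest intervening edges) can date a node *below* the age
of a deeper, older landmark elsewhere in its subtree — a negative branch —
even when the landmark set is perfectly self-consistent. phylospat
therefore anchors each chain on the **oldest** dated descendant reachable
through undated nodes (ties: nearest, then lowest node number). Because
every node interpolated on such a chain ends up older than the oldest dated
node anywhere below it, parent ages always exceed child ages for any
consistent landmark set; pure chains (a single dated descendant) are
unaffected.

## Diversity and endemism metrics

All metrics operate on a tree pruned to the analyzed species set
(`prune_to_species()`), which collapses unary nodes by summing lengths but
accumulates the original root-to-MRCA path into the tree's root edge —
pruning therefore changes no patristic distance and no PD value.

* **PD** (`faith_pd()`) is the summed branch length of the minimal subtree
  spanning a cell's species. The path up to the root is included by default:
  this makes single-species PD well defined (its root-to-tip path), makes
  PD of the full species set equal the total tree length, and matches the
  convention of the standard biodiversity-analysis tools for gridded data.
  An `include_root = FALSE` flag restricts to branches below the MRCA.
* **PE** (`phylogenetic_endemism()`) is PD with each branch divided by its
  range size $R(b)$, the number of cells holding at least one of its
  descendant species. A branch confined to one cell contributes its full
  length there; a ubiquitous branch is shared out across all cells.
  Summed over cells, PE returns exactly the total tree branch length
  (every branch's contributions are $R(b)$ shares of $1/R(b)$ each), and
  $PE \le PD$ cell-wise since $R(b) \ge 1$. Ranges are counted over the
  analyzed grid only — no correction for range extents outside the study
  area, which would only lower PE for species whose distributions continue
  beyond it.
* **WE** (`weighted_endemism()`) is the species-level analogue: the sum of
  inverse range sizes over a cell's species; it sums over cells to the
  species count.
* **MPD / MNTD** are the mean pairwise and mean nearest-neighbor patristic
  distances among a cell's species, each unordered pair (or species)
  counted once. They are undefined for single-species cells, which are
  reported as missing rather than zero.
* **Sorensen dissimilarity** between regional pools,
  $D = 1 - 2|P_r \cap P_s| / (|P_r| + |P_s|)$, supports checking that a
  regionalization groups floristically coherent areas.

## Null models and standardized structure

Observed MPD and MNTD are standardized against null assemblages of
identical richness drawn uniformly from a species pool: the continental
pool (every species in the analyzed set) or the pool of the cell's region.
The standardized score is $z = -(\mathrm{obs} - \mu_0)/\sigma_0$ — the Net
Relatedness Index for MPD, Nearest Taxon Index for MNTD — so positive
values mean co-occurring species are *more* related than random draws
(clustering, as under environmental filtering) and negative values less
related (evenness, as where distant lineages co-occur in refugia).
$\sigma_0$ is the sample ($n-1$) standard deviation, which is what an
exhaustive enumeration of all $\binom{N}{S}$ subsets reproduces.

Null distributions are computed once per (pool, richness) combination and
shared by every cell of that richness in the pool. Draws never re-use a
sample combination (canonical sorted-key tracking, with an explicit memory
cap), so a run stops for one of three recorded reasons: `max_iterations`
(default 4999 draws), `combinations_exhausted` (all $\binom{N}{S}$ subsets
seen — with non-reuse, the empirical null is then exactly the complete
enumeration), or `converged`. The convergence rule is applied from
iteration 500 onward over the trailing 100 scores. Its published phrasing —
stop when the *ratio of minimum to maximum* score is below 0.005 — is
implemented literally as the default, but note that for a window of similar
positive MPD values this ratio is near 1, so the literal rule essentially
never fires; a `relative_range` mode (stop when $1 - \min/\max < 0.005$,
i.e. the window is nearly constant) is provided as the plausible intent.
Neither reading is silently substituted for the other; the mode in force is
recorded in the audit table. Cells whose richness equals their pool size
admit a single draw, $\sigma_0 = 0$: their score is reported missing and
the cell classed `neutral_degenerate` rather than dividing by zero.

Classification thresholds are configurable because the source analyses do
not state theirs: defaults are $|z| \ge 1.96$ for significant and
$|z| \ge 1$ for weak structure, the sign separating clustering from
evenness. No multiple-testing correction is applied across cells.

Reproducibility: each (pool, richness) null distribution is seeded by a
hash of the pool's sorted species labels plus the richness, folded into the
master seed. Results are therefore bit-identical across runs with the same
seed and configuration, independent of cell or pool iteration order — and a
regional pool that happens to contain exactly the continental species set
yields exactly the continental results.

## The synthetic-landscape generator

The generator exists so the full pipeline can be validated with data whose
true structure is known. It emulates the statistical skeleton the analysis
assumes: a clade-structured ultrametric phylogeny (pure-birth, root scaled
to age 100; extinction would add nothing to the test surface); two
orthogonal linear environmental gradients (moisture along x, temperature
along y, each spanning [0, 1], echoing a wet–dry by tropical–temperate
continental layout); species niche optima evolved by Brownian motion on the
tree, mixed with an independent uniform draw by the `niche_signal` weight
(1 = full phylogenetic conservatism, 0 = none); and a partition of the grid
into labeled regions.

Three assembly scenarios generate occurrences:

* **filtering** — a species occupies the cells whose moisture and
  temperature both lie within `tolerance` (default 0.18) of its optima,
  plus a uniform jitter up to `occupancy_noise` (default 0.05) per
  species-cell test. With conserved niches, relatives share cells and
  assemblages cluster phylogenetically. The default tolerance was chosen so
  that median cell richness is near 20 species at the default landscape
  (150 species, 20 × 20 cells of 10 km), which keeps null-model runtime
  modest while populating many richness classes; a species matching no cell
  is placed in its nearest-by-niche cell so every species occurs somewhere.
* **neutral** — every species occupies the same number of uniformly random
  cells (default targets mean richness 20). Conditional on richness a
  cell's composition is then a uniform subset of the pool, which is exactly
  the null model's assumption — this scenario is the calibration standard:
  about 5% of cells should be flagged significant at $|z| \ge 1.96$ and
  mean NRI should be near 0, which the acceptance checks verify.
* **refugia** — background species are endemic to one region each (home
  region drawn proportional to region area, each species occupying the
  same *fraction* of its region that a neutral species occupies of the
  grid, so expected richness is comparable across regions of any size),
  and designated refugial blocks additionally hold one representative of
  each of `refugium_lineage_count` (default 8) maximally distant lineages,
  selected by greedy maximin on patristic distance. The representatives
  occur nowhere else, so refugial cells mix distant lineages (evenness
  against continental nulls) and concentrate geographically restricted
  branch length (elevated PE).

The regionalized background is what makes regional-pool contrasts
meaningful: when the refugium is its own region, the regional pool is
dominated by the relict lineages themselves, null draws resemble the
observed assemblages, and the evenness signal weakens relative to the
continental analysis — the behavior expected where an isolated refugial
region (a Tasmania-like situation) is judged against its own flora. An
earlier design in which background species ranged over the whole grid made
regional pools nearly identical to the continental one, and a design with a
large refugial region shrank regional null SDs faster than it moved the
null mean, *inflating* regional scores; both fail to express the intended
mechanism, which is why the generator regionalizes the background and the
attenuation checks define the refugial region as the refugium.

All generator randomness flows from one master seed through documented
substreams (`sub_seed()`): tree, niche optima, occupancy, taxonomy, and
each null distribution draw from separate streams, so any component can be
regenerated independently and fixtures are bit-reproducible.

What the generator does **not** emulate: real coastline geometry, spatially
autocorrelated sampling effort or record error, abundance structure,
gradients that interact or bend, extinction, or cross-regional range
continuity. Passing the scenario checks therefore demonstrates that the
pipeline recovers known structure of the kinds it models — not that any
particular empirical landscape will show these patterns.

## Validation problem sizes

The test suite validates the metric layer exactly (tolerance $10^{-9}$)
against independent brute-force enumerations on dozens of random trees of
up to 15 tips and grids of up to 20 cells, and the null layer against
complete $\binom{N}{S}$ enumerations for pools up to 12 species. The
stochastic properties use a neutral landscape of 400 cells with 999 draws
per richness class, and 20 replicate landscapes of 144 cells (80 species,
199 draws per class) for the filtering/refugia contrast — sizes chosen to
exercise every code path at desk scale. `scripts/acceptance.R` re-runs the
same battery from a single command-line seed.

## Known limitations

* Non-monophyletic genera cannot be expressed in grafting; a species whose
  genus label is absent attaches at its family, and conflicting genus
  placements across source taxonomies must be resolved upstream (one
  assignment per species).
* Age interpolation is purely topological: it uses no molecular rates, and
  two sister chains with different true depths but identical landmark
  structure receive identical interpolated ages.
* PE and WE ranges are counted over the analyzed grid; ranges extending
  beyond the study area are not discounted.
* The literal convergence rule is kept for fidelity even though it is
  essentially inert on MPD-scale scores (see above).
* Null draws are uniform; trial-swap and frequency-weighted null models
  are out of scope.
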