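#' Scenario configuration for the synthetic-landscape generator
#'
#' Describes a rectangular landscape crossed by two orthogonal linear
#' environmental gradients — moisture increasing along x, temperature
#' along y, each spanning \[0, 1\] — a clade-structured species pool whose
#' niche optima evolve on a simulated tree, and one of three assembly
#' scenarios:
#'
#' * `"filtering"` — a species occupies a cell when the cell's moisture
#'   and temperature both fall within a tolerance band of its optima, so
#'   related species (under phylogenetic niche conservatism,
#'   `niche_signal` near 1) share habitats and assemblages cluster
#'   phylogenetically.
#' * `"refugia"` — random background occupancy, plus designated refugial
#'   cell blocks seeded with one representative of each of
#'   `refugium_lineage_count` maximally distant lineages; those species
#'   occur nowhere else, so refugial cells mix distant lineages (phylo-
#'   genetic evenness) and concentrate range-restricted branch length
#'   (high phylogenetic endemism).
#' * `"neutral"` — every species occupies `neutral_occupancy` cells
#'   uniformly at random, so assemblages are uniform richness-preserving
#'   draws from the pool and no phylogenetic structure is expected.
#'
#' Defaults give a 20 x 20 grid of 10 km cells, 150 species, and a
#' filtering tolerance of 0.18 chosen so that median cell richness is
#' about 20 species, which keeps null-model runtimes modest while leaving
#' every richness class well populated.
#'
#' @param scenario one of `"filtering"`, `"refugia"`, `"neutral"`.
#' @param n_species number of species on the simulated tree.
#' @param n_cells_x,n_cells_y grid dimensions (cells).
#' @param cell_size cell edge length in meters.
#' @param origin grid origin in meters.
#' @param niche_signal strength of phylogenetic conservatism of niche
#'   optima in \[0, 1\]: 0 = optima independent of the tree, 1 = pure
#'   Brownian motion.
#' @param tolerance half-width of the occupancy band on each gradient.
#' @param occupancy_noise upper bound of the uniform jitter added to the
#'   tolerance per species-cell test (>= 0).
#' @param refugia list of cell blocks, each `list(i_range = c(lo, hi),
#'   j_range = c(lo, hi))` in cell indices; default one 3 x 3 block in
#'   the second region.
#' @param refugium_lineage_count number of maximally distant lineages
#'   seeded into each refugial block.
#' @param neutral_occupancy cells occupied per species in the neutral and
#'   refugia scenarios; default targets mean richness of about 20.
#' @param regions named list of rectangular blocks (same form as
#'   `refugia`) partitioning the grid; default splits it into `west` and
#'   `east` halves.
#' @param seed master seed; all generator randomness derives from it via
#'   [sub_seed()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("filtering", "refugia", "neutral"),
                            n_species = 150L, n_cells_x = 20L, n_cells_y = 20L,
                            cell_size = 10000, origin = c(0, 0),
                            niche_signal = 1, tolerance = 0.18,
                            occupancy_noise = 0.05,
                            refugia = NULL, refugium_lineage_count = 8L,
                            neutral_occupancy = NULL, regions = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_species >= 2, n_cells_x >= 1, n_cells_y >= 1, cell_size > 0,
            niche_signal >= 0, niche_signal <= 1, tolerance > 0,
            occupancy_noise >= 0, refugium_lineage_count >= 2)
  n_cells <- n_cells_x * n_cells_y
  if (is.null(regions)) {
    half <- max(1L, n_cells_x %/% 2L)
    regions <- list(
      west = list(i_range = c(0L, half - 1L), j_range = c(0L, n_cells_y - 1L)),
      east = list(i_range = c(half, n_cells_x - 1L), j_range = c(0L, n_cells_y - 1L)))
  }
  if (is.null(refugia)) {
    lo_i <- max(0L, n_cells_x - 4L); lo_j <- min(1L, n_cells_y - 1L)
    refugia <- list(list(i_range = c(lo_i, min(lo_i + 2L, n_cells_x - 1L)),
                         j_range = c(lo_j, min(lo_j + 2L, n_cells_y - 1L))))
  }
  if (is.null(neutral_occupancy))
    neutral_occupancy <- max(2L, round(20 * n_cells / n_species))
  cfg <- list(scenario = scenario, n_species = as.integer(n_species),
              n_cells_x = as.integer(n_cells_x), n_cells_y = as.integer(n_cells_y),
              cell_size = cell_size, origin = origin,
              niche_signal = niche_signal, tolerance = tolerance,
              occupancy_noise = occupancy_noise, refugia = refugia,
              refugium_lineage_count = as.integer(refugium_lineage_count),
              neutral_occupancy = as.integer(neutral_occupancy),
              regions = regions, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_blocks(cfg)
  cfg
}

# regions must cover each cell exactly once; refugia must lie inside the grid
validate_blocks <- function(cfg) {
  covered <- matrix(0L, cfg$n_cells_x, cfg$n_cells_y)
  for (b in cfg$regions) {
    ii <- b$i_range[1L]:b$i_range[2L] + 1L
    jj <- b$j_range[1L]:b$j_range[2L] + 1L
    if (any(ii < 1L) || any(ii > cfg$n_cells_x) ||
        any(jj < 1L) || any(jj > cfg$n_cells_y))
      stop("region block outside the grid")
    covered[ii, jj] <- covered[ii, jj] + 1L
  }
  if (any(covered != 1L)) stop("regions must partition the grid exactly once")
  for (b in cfg$refugia)
    if (b$i_range[1L] < 0L || b$i_range[2L] >= cfg$n_cells_x ||
        b$j_range[1L] < 0L || b$j_range[2L] >= cfg$n_cells_y)
      stop("refugium block outside the grid")
  invisible(cfg)
}

block_keys <- function(blocks) {
  unlist(lapply(blocks, function(b) {
    g <- expand.grid(i = b$i_range[1L]:b$i_range[2L],
                     j = b$j_range[1L]:b$j_range[2L])
    cell_key(g$i, g$j)
  }), use.names = FALSE)
}

#' Simulate an ultrametric pure-birth tree
#'
#' Constant-rate birth (Yule) tree on `n_species` extant tips, rescaled
#' so the root age is `root_age` (default 100 time units); tips are
#' labeled `sp0001`, `sp0002`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed (fixed seed gives an identical tree).
#' @param root_age depth of the root after rescaling.
#' @return A `phylo` object, ultrametric to numerical precision.
#' @export
simulate_tree <- function(n_species, seed = 1L, root_age = 100) {
  stopifnot(n_species >= 2, root_age > 0)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(node_depths(tree)[seq_len(n_species)])
  tree$edge.length <- tree$edge.length * root_age / depth
  tree$tip.label <- sprintf("sp%04d", seq_len(n_species))
  tree
}

#' Evolve niche optima along a tree
#'
#' Each species receives a moisture and a temperature optimum in \[0, 1\]
#' as a mixture of a Brownian-motion trait simulated on the tree
#' (min-max rescaled to \[0, 1\]) and an independent uniform draw:
#' `opt = niche_signal * BM + (1 - niche_signal) * U(0, 1)`. With
#' `niche_signal = 0` the optima carry no phylogenetic signal; with 1
#' they are purely Brownian, so close relatives have similar niches.
#'
#' @param tree an ultrametric `phylo` object.
#' @param niche_signal mixture weight in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with columns `species`, `moisture_opt`, `temp_opt`.
#' @export
evolve_niche <- function(tree, niche_signal, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), niche_signal >= 0, niche_signal <= 1)
  set.seed(seed)
  n <- length(tree$tip.label)
  rescale01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1L]) / diff(r)
  }
  bm_m <- rescale01(phytools::fastBM(tree))[tree$tip.label]
  bm_t <- rescale01(phytools::fastBM(tree))[tree$tip.label]
  data.frame(
    species = tree$tip.label,
    moisture_opt = niche_signal * bm_m + (1 - niche_signal) * runif(n),
    temp_opt = niche_signal * bm_t + (1 - niche_signal) * runif(n),
    row.names = NULL, stringsAsFactors = FALSE)
}

# greedy maximin selection of k mutually distant tips on the tree
distant_lineages <- function(tree, k) {
  D <- patristic_matrix(tree)
  pick <- which(D == max(D), arr.ind = TRUE)[1L, ]
  chosen <- rownames(D)[pick]
  while (length(chosen) < k) {
    rest <- setdiff(rownames(D), chosen)
    mind <- apply(D[rest, chosen, drop = FALSE], 1L, min)
    chosen <- c(chosen, rest[which.max(mind)])
  }
  chosen
}

#' Assemble synthetic occurrence records for a scenario
#'
#' Turns the landscape, the tree and the niche optima into point
#' occurrence records (one record per species per occupied cell, at the
#' cell center), following the configured assembly scenario (see
#' [scenario_config()] for the three scenarios). Every species is
#' guaranteed at least one occurrence: a filtering species whose
#' tolerance band matches no cell is placed in the cell closest to its
#' optima. The `region` column is filled from the configured region
#' blocks.
#'
#' @param config a [scenario_config()].
#' @param tree the simulated phylogeny (see [simulate_tree()]).
#' @param optima niche optima table (see [evolve_niche()]); ignored by
#'   the neutral scenario.
#' @return data.frame with columns `species`, `x`, `y`, `region`.
#' @export
assemble_occurrences <- function(config, tree, optima = NULL) {
  stopifnot(inherits(config, "scenario_config"), inherits(tree, "phylo"))
  set.seed(sub_seed(config$seed, 3L))
  nx <- config$n_cells_x; ny <- config$n_cells_y
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  moist_c <- (cells$i + 0.5) / nx
  temp_c <- (cells$j + 0.5) / ny
  n_cells <- nrow(cells)
  spp <- tree$tip.label
  n_sp <- length(spp)
  occ <- matrix(FALSE, n_sp, n_cells, dimnames = list(spp, NULL))

  region_by_cell <- rep(NA_character_, n_cells)
  for (nm in names(config$regions)) {
    b <- config$regions[[nm]]
    inb <- cells$i >= b$i_range[1L] & cells$i <= b$i_range[2L] &
           cells$j >= b$j_range[1L] & cells$j <= b$j_range[2L]
    region_by_cell[inb] <- nm
  }

  neutral_fill <- function(occ, for_species, within = seq_len(n_cells)) {
    k <- min(config$neutral_occupancy, length(within))
    for (s in for_species) occ[s, within[sample.int(length(within), k)]] <- TRUE
    occ
  }

  if (config$scenario == "filtering") {
    if (is.null(optima)) stop("filtering scenario requires niche optima")
    mo <- optima$moisture_opt[match(spp, optima$species)]
    to <- optima$temp_opt[match(spp, optima$species)]
    for (s in seq_len(n_sp)) {
      tol_m <- config$tolerance + runif(n_cells, 0, config$occupancy_noise)
      tol_t <- config$tolerance + runif(n_cells, 0, config$occupancy_noise)
      occ[s, ] <- abs(moist_c - mo[s]) < tol_m & abs(temp_c - to[s]) < tol_t
      if (!any(occ[s, ]))
        occ[s, which.min(pmax(abs(moist_c - mo[s]), abs(temp_c - to[s])))] <- TRUE
    }
  } else if (config$scenario == "neutral") {
    occ <- neutral_fill(occ, spp)
  } else {   # refugia
    # background species are endemic to one region each (regionalized
    # floras, so regional pools are proper subsets of the continental
    # pool); home regions are drawn with probability proportional to
    # region area and each species occupies the same *fraction* of its
    # region as a neutral species does of the whole grid, keeping
    # expected cell richness comparable across regions of any size.
    # Refugial blocks additionally hold the distant lineages, which
    # occur nowhere else.
    reps <- distant_lineages(tree, min(config$refugium_lineage_count, n_sp))
    bg <- setdiff(spp, reps)
    sizes <- vapply(names(config$regions), function(nm)
      sum(region_by_cell == nm), numeric(1))
    home <- sample(names(config$regions), length(bg), replace = TRUE,
                   prob = sizes / sum(sizes))
    frac <- min(1, config$neutral_occupancy / n_cells)
    for (nm in names(config$regions)) {
      within <- which(region_by_cell == nm)
      k <- max(1L, min(length(within), ceiling(frac * length(within))))
      for (s in bg[home == nm])
        occ[s, within[sample.int(length(within), k)]] <- TRUE
    }
    ref_keys <- block_keys(config$refugia)
    ref_cells <- match(ref_keys, cell_key(cells$i, cells$j))
    occ[reps, ref_cells] <- TRUE
    for (s in bg)                      # guard against an all-empty row
      if (!any(occ[s, ])) occ[s, sample.int(n_cells, 1L)] <- TRUE
  }

  hit <- which(occ, arr.ind = TRUE)
  out <- data.frame(
    species = spp[hit[, 1L]],
    x = config$origin[1L] + (cells$i[hit[, 2L]] + 0.5) * config$cell_size,
    y = config$origin[2L] + (cells$j[hit[, 2L]] + 0.5) * config$cell_size,
    region = region_by_cell[hit[, 2L]],
    stringsAsFactors = FALSE)
  out <- out[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running the full generator with substream seeds
#' derived from the master seed: tree, niche optima, occurrence records,
#' and the gridded assemblages (richness filter applied for the
#' filtering/neutral scenarios is left to the caller).
#'
#' @param config a [scenario_config()].
#' @return List with `tree`, `optima`, `occurrences`, `grid` (an
#'   `assemblage_grid` at the configured cell size, with regions), and
#'   `refugial_keys` (cell keys of the refugial blocks).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- simulate_tree(config$n_species, sub_seed(config$seed, 1L))
  optima <- evolve_niche(tree, config$niche_signal, sub_seed(config$seed, 2L))
  occurrences <- assemble_occurrences(config, tree, optima)
  grid <- grid_occurrences(occurrences, config$cell_size, config$origin)
  list(tree = tree, optima = optima, occurrences = occurrences, grid = grid,
       refugial_keys = block_keys(config$refugia), config = config)
}

#' Simulate a taxonomy table for a tree
#'
#' Groups tips into genera and families by cutting a clustering of the
#' patristic distances (families nest genera), and assigns growth forms
#' at a fixed freestanding:climbing ratio — enough structure to exercise
#' grafting and growth-form species-set selection.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param seed integer seed (growth-form assignment).
#' @param genus_size,family_size target mean tips per genus / family.
#' @param climbing_frac fraction of climbing species.
#' @return data.frame `species`, `genus`, `family`, `growth_form`.
#' @export
simulate_taxonomy <- function(tree, seed = 1L, genus_size = 4, family_size = 20,
                              climbing_frac = 0.2) {
  set.seed(seed)
  n <- length(tree$tip.label)
  hc <- stats::hclust(stats::as.dist(patristic_matrix(tree)), method = "average")
  gk <- max(2L, min(n, ceiling(n / genus_size)))
  fk <- max(1L, min(gk, ceiling(n / family_size)))
  genus <- sprintf("gen%03d", stats::cutree(hc, k = gk))
  family <- sprintf("fam%03d", stats::cutree(hc, k = fk))
  data.frame(
    species = tree$tip.label, genus = genus, family = family,
    growth_form = ifelse(runif(n) < climbing_frac, "climbing", "freestanding"),
    stringsAsFactors = FALSE)
}
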