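# Shared substrate: per-node counts of how many of each cell's species lie
# below each node. Row order: ape node numbering (tips first); columns:
# grid cell keys.
presence_counts <- function(tree, grid) {
  sp <- grid_species(grid)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("grid species not in tree: ", paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  keys <- names(grid$cells)
  cnt <- matrix(0L, nnode, length(keys), dimnames = list(NULL, keys))
  for (k in seq_along(keys))
    cnt[match(grid$cells[[k]], tree$tip.label), k] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge)))
    cnt[ord$edge[e, 1L], ] <- cnt[ord$edge[e, 1L], ] + cnt[ord$edge[e, 2L], ]
  cnt
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of branch lengths of the minimal subtree spanning the species.
#' By default the path up to the root (including any root edge) is part
#' of the subtree, which makes single-species PD well defined (its
#' root-to-tip path length) and makes PD of the full tip set equal
#' [total_branch_length()]; set `include_root = FALSE` to count only
#' branches below the species' MRCA.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param species nonempty character vector of tip labels.
#' @param include_root include the MRCA-to-root path (default TRUE).
#' @return PD in branch-length units.
#' @export
faith_pd <- function(tree, species, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  species <- unique(as.character(species))
  if (length(species) == 0L) stop("species set must be nonempty")
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("PD requires all branch lengths present")
  ntip <- length(tree$tip.label)
  parent_edge <- integer(ntip + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  marked <- logical(nrow(tree$edge))
  for (tip in match(species, tree$tip.label)) {
    nd <- tip
    while (parent_edge[nd] && !marked[parent_edge[nd]]) {
      marked[parent_edge[nd]] <- TRUE
      nd <- tree$edge[parent_edge[nd], 1L]
    }
  }
  if (include_root)
    return(sum(tree$edge.length[marked]) + max(0, tree$root.edge %||% 0))
  if (length(species) == 1L) return(0)
  mrca <- ape::getMRCA(tree, species)
  nd <- mrca
  while (parent_edge[nd]) {
    marked[parent_edge[nd]] <- FALSE
    nd <- tree$edge[parent_edge[nd], 1L]
  }
  sum(tree$edge.length[marked])
}

#' Branch range sizes over a grid
#'
#' For every branch of the tree, the number of grid cells containing at
#' least one descendant species — the range size R(b) that down-weights
#' branch lengths in phylogenetic endemism.
#'
#' @param tree a `phylo` object whose tips cover the grid's species.
#' @param grid an `assemblage_grid`.
#' @return data.frame with one row per edge: `parent`, `child`, `length`,
#'   `range`. Attribute `n_occupied` gives the number of cells (the range
#'   of the root edge, when one exists).
#' @export
branch_ranges <- function(tree, grid) {
  cnt <- presence_counts(tree, grid)
  occ <- cnt[tree$edge[, 2L], , drop = FALSE] > 0L
  out <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                    length = tree$edge.length %||% rep(NA_real_, nrow(tree$edge)),
                    range = as.integer(rowSums(occ)))
  attr(out, "n_occupied") <- ncol(cnt)
  out
}

#' Phylogenetic endemism per cell
#'
#' Rosauer-style PE: for each cell, the branch lengths of its spanning
#' subtree (root path included, matching the PD convention) are summed
#' after dividing each branch by its range size R(b) — the number of
#' cells holding any of its descendants. A branch wholly restricted to
#' one cell contributes its full length there; widespread branches are
#' shared out, so PE sums over cells to the total tree branch length and
#' PE(cell) <= PD(cell) always. PE is computed relative to the analyzed
#' grid only (ranges are counted over its cells).
#'
#' @param tree a `phylo` object with branch lengths, tips covering the
#'   grid's species (prune first with [prune_to_species()] if not).
#' @param grid an `assemblage_grid`.
#' @param include_root include each cell's MRCA-to-root path and the root
#'   edge (default TRUE, as for [faith_pd()]).
#' @return Named numeric vector of PE by cell key.
#' @export
phylogenetic_endemism <- function(tree, grid, include_root = TRUE) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("PE requires all branch lengths present")
  cnt <- presence_counts(tree, grid)
  S <- cell_richness(grid)[colnames(cnt)]
  child_cnt <- cnt[tree$edge[, 2L], , drop = FALSE]
  occ <- child_cnt > 0L
  if (!include_root)                       # drop edges at/above each cell's MRCA
    occ <- occ & sweep(child_cnt, 2L, S, `<`)
  rng <- rowSums(child_cnt > 0L)
  w <- ifelse(rng > 0L, tree$edge.length / pmax(rng, 1L), 0)
  pe <- colSums(occ * w)
  if (include_root)
    pe <- pe + max(0, tree$root.edge %||% 0) / ncol(cnt)
  pe
}

#' Weighted endemism per cell
#'
#' Sum over the species of a cell of the inverse of their range size
#' (number of cells occupied): a species found nowhere else contributes
#' 1, a widespread one close to 0. Sums over cells to the species count.
#'
#' @param grid an `assemblage_grid`.
#' @return Named numeric vector of WE by cell key.
#' @export
weighted_endemism <- function(grid) {
  sp <- grid_species(grid)
  rng <- setNames(integer(length(sp)), sp)
  for (s in grid$cells) rng[s] <- rng[s] + 1L
  vapply(grid$cells, function(s) sum(1 / rng[s]), numeric(1))
}

#' Mean pairwise phylogenetic distance
#'
#' Mean patristic distance over unordered distinct pairs of the species
#' present (presence-weighted: each pair counted once).
#'
#' @param dist patristic distance matrix (see [patristic_matrix()]).
#' @param species character vector of at least two tip labels.
#' @return MPD in branch-length units.
#' @export
mpd <- function(dist, species) {
  species <- unique(as.character(species))
  if (length(species) < 2L) stop("MPD requires at least 2 species")
  sub <- dist[species, species, drop = FALSE]
  mean(sub[lower.tri(sub)])
}

#' Mean nearest-taxon phylogenetic distance
#'
#' Mean, over the species present, of each species' patristic distance
#' to its closest co-occurring relative. Always <= MPD.
#'
#' @inheritParams mpd
#' @return MNTD in branch-length units.
#' @export
mntd <- function(dist, species) {
  species <- unique(as.character(species))
  if (length(species) < 2L) stop("MNTD requires at least 2 species")
  sub <- dist[species, species, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' Sorensen dissimilarity between regional species pools
#'
#' D(r, s) = 1 - 2|P(r) n P(s)| / (|P(r)| + |P(s)|), zero diagonal.
#'
#' @param pools named list of species sets (see [regional_pools()]).
#' @return Symmetric matrix with region names as dimnames.
#' @export
sorensen_matrix <- function(pools) {
  if (length(pools) < 2L) stop("need at least 2 pools")
  n <- length(pools)
  D <- matrix(0, n, n, dimnames = list(names(pools), names(pools)))
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    inter <- length(intersect(pools[[a]], pools[[b]]))
    D[a, b] <- D[b, a] <-
      1 - 2 * inter / (length(pools[[a]]) + length(pools[[b]]))
  }
  D
}

#' Per-cell diversity metrics table
#'
#' Computes richness S, PD, PE and WE for every cell, and MPD/MNTD for
#' cells with S >= 2 (reported as missing for single-species cells, where
#' pairwise metrics are undefined). The tree is pruned to the grid's
#' species first, preserving the root path, so PD/PE conventions match
#' across species sets. Columns NRI/NTI/class are left missing; they are
#' filled by [run_nri_analysis()].
#'
#' @param grid an `assemblage_grid`.
#' @param tree a `phylo` object with branch lengths covering the grid's
#'   species.
#' @param include_root root-path convention for PD/PE (default TRUE).
#' @return data.frame, one row per cell: `cell_i`, `cell_j`, `region`,
#'   `S`, `PD`, `PE`, `WE`, `MPD`, `MNTD`, `NRI`, `NTI`, `class`.
#' @export
cell_metrics <- function(grid, tree, include_root = TRUE) {
  stopifnot(inherits(grid, "assemblage_grid"), inherits(tree, "phylo"))
  sp <- grid_species(grid)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing))
    stop("grid species not in tree: ", paste(head(missing, 5L), collapse = ", "))
  if (length(sp) < length(tree$tip.label))
    tree <- prune_to_species(tree, sp)
  ix <- cell_indices(grid)
  S <- unname(cell_richness(grid))
  pe <- phylogenetic_endemism(tree, grid, include_root = include_root)
  we <- weighted_endemism(grid)
  pd <- vapply(grid$cells, function(s) faith_pd(tree, s, include_root), numeric(1))
  D <- patristic_matrix(tree)
  mpd_v <- mntd_v <- rep(NA_real_, length(S))
  for (k in which(S >= 2L)) {
    mpd_v[k] <- mpd(D, grid$cells[[k]])
    mntd_v[k] <- mntd(D, grid$cells[[k]])
  }
  data.frame(
    cell_i = ix$i, cell_j = ix$j,
    region = if (is.null(grid$regions)) NA_character_ else unname(grid$regions),
    S = S, PD = unname(pd), PE = unname(pe), WE = unname(we),
    MPD = mpd_v, MNTD = mntd_v,
    NRI = NA_real_, NTI = NA_real_, class = NA_character_,
    stringsAsFactors = FALSE)
}

#' Write a cell metrics table as delimited text
#'
#' One row per cell, missing values as empty fields, numbers in a fixed
#' format so identical runs produce byte-identical files.
#'
#' @param metrics data.frame from [cell_metrics()] / [run_nri_analysis()].
#' @param file output path.
#' @export
write_metrics <- function(metrics, file) {
  out <- metrics
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !cl %in% c("cell_i", "cell_j", "S"))
      out[[cl]] <- fmt_num(out[[cl]])
  out[is.na(out)] <- ""
  write_atomic(file, function(p)
    write.csv(out, p, row.names = FALSE, quote = FALSE))
}
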