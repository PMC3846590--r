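# Independent brute-force oracles. These deliberately take different routes
# from the package implementation: descendant sets are found by recursion
# over an adjacency list, pair distances by depth + explicit MRCA search,
# ranges by naive per-cell loops.

# list of tip index sets below the child of every edge
oracle_edge_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], below), use.names = FALSE)
  }
  lapply(tree$edge[, 2], below)
}

oracle_node_depth <- function(tree) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(length(parent))
  elen[tree$edge[, 2]] <- tree$edge.length
  vapply(seq_along(parent), function(nd) {
    d <- 0
    while (parent[nd] != 0) { d <- d + elen[nd]; nd <- parent[nd] }
    d
  }, numeric(1))
}

oracle_ancestors <- function(tree, node) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anc <- node
  while (parent[node] != 0) { node <- parent[node]; anc <- c(anc, node) }
  anc
}

oracle_patristic <- function(tree) {
  tips <- tree$tip.label
  depth <- oracle_node_depth(tree)
  D <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (a in seq_along(tips)) for (b in seq_along(tips)) {
    if (a == b) next
    mrca_depth <- max(depth[intersect(oracle_ancestors(tree, a),
                                      oracle_ancestors(tree, b))])
    D[a, b] <- depth[a] + depth[b] - 2 * mrca_depth
  }
  D
}

oracle_pd <- function(tree, species, include_root = TRUE) {
  desc <- oracle_edge_descendants(tree)
  sp_idx <- match(species, tree$tip.label)
  hit <- vapply(desc, function(d) length(intersect(d, sp_idx)) > 0, logical(1))
  if (!include_root) {
    above <- vapply(desc, function(d) all(sp_idx %in% d), logical(1))
    return(sum(tree$edge.length[hit & !above]))
  }
  sum(tree$edge.length[hit]) + max(0, if (is.null(tree$root.edge)) 0 else tree$root.edge)
}

oracle_pe <- function(tree, grid) {
  desc <- oracle_edge_descendants(tree)
  cells <- grid$cells
  pe <- setNames(numeric(length(cells)), names(cells))
  for (e in seq_along(desc)) {
    labels_below <- tree$tip.label[desc[[e]]]
    in_cell <- vapply(cells, function(s) length(intersect(s, labels_below)) > 0,
                      logical(1))
    R <- sum(in_cell)
    if (R > 0) pe[in_cell] <- pe[in_cell] + tree$edge.length[e] / R
  }
  re <- if (is.null(tree$root.edge)) 0 else max(0, tree$root.edge)
  pe + re / length(cells)
}

oracle_we <- function(grid) {
  vapply(grid$cells, function(s) {
    sum(vapply(s, function(sp)
      1 / sum(vapply(grid$cells, function(cc) sp %in% cc, logical(1))),
      numeric(1)))
  }, numeric(1))
}

oracle_mpd <- function(D, species) {
  tot <- 0; n <- 0
  for (a in seq_along(species)) for (b in seq_along(species)) if (a < b) {
    tot <- tot + D[species[a], species[b]]; n <- n + 1
  }
  tot / n
}

oracle_mntd <- function(D, species) {
  mean(vapply(species, function(a)
    min(vapply(setdiff(species, a), function(b) D[a, b], numeric(1))),
    numeric(1)))
}

# exhaustive richness-preserving null z-score (clustering-positive sign)
oracle_exhaustive_z <- function(D, pool, S, obs_fn) {
  combos <- combn(pool, S, simplify = FALSE)
  scores <- vapply(combos, obs_fn, numeric(1))
  list(mean = mean(scores), sd = sd(scores),
       z = function(obs) -(obs - mean(scores)) / sd(scores))
}

# random fixtures -------------------------------------------------------

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)                     # uniform branch lengths in (0, 1)
  tr$edge.length <- round(tr$edge.length, 6)
  tr
}

# random grid over the tips of a tree; every cell nonempty, every species
# placed somewhere
random_grid <- function(species, n_cells, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    cells <- lapply(seq_len(n_cells), function(i)
      sample(species, sample(seq_along(species), 1)))
    if (all(species %in% unlist(cells))) break
  }
  names(cells) <- cell_key(seq_len(n_cells) - 1L, 0L)
  assemblage_grid(cells, cell_size = 10000)
}

# straight root->...->tip chain with labeled internal nodes (built directly:
# the Newick reader renumbers unary chains)
chain_tree <- function(labels) {
  n <- length(labels)
  edge <- cbind(2:(n + 1L), c(if (n > 1) 3:(n + 1L), 1L))
  structure(list(edge = edge, Nnode = n, tip.label = "t",
                 edge.length = rep(1, n), node.label = labels),
            class = "phylo")
}
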