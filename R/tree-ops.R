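#' Prune a phylogeny to a species set
#'
#' Drops all tips not in `keep`, collapsing the resulting unary internal
#' nodes by summing their branch lengths. The original root is retained:
#' the path from it down to the MRCA of the kept tips is accumulated into
#' the tree's `root.edge`, so root-inclusive PD conventions are stable
#' under pruning. Patristic distances among the kept tips are preserved
#' exactly.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param keep character vector of tip labels to retain (at least one).
#' @return A `phylo` object whose tips are exactly `keep`.
#' @export
prune_to_species <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  if (length(keep) < 1L) stop("`keep` must contain at least one species")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)

  if (length(keep) == 1L) {
    # single-tip tree: one edge carrying the full root-to-tip path length
    depth <- node_depths(tree)[match(keep, tree$tip.label)]
    out <- list(edge = matrix(c(2L, 1L), 1L, 2L),
                edge.length = unname(depth),
                Nnode = 1L, tip.label = keep)
    if (!is.null(tree$root.edge)) out$root.edge <- tree$root.edge
    class(out) <- "phylo"
    return(out)
  }

  drop <- setdiff(tree$tip.label, keep)
  sub <- ape::drop.tip(tree, drop, collapse.singles = FALSE)
  collapse_singles_keep_rootpath(sub)
}

# collapse unary internal nodes, summing branch lengths; the unary chain at
# the root (root-to-first-split path) is accumulated into $root.edge
collapse_singles_keep_rootpath <- function(tree) {
  root.extra <- 0
  repeat {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    kids <- which(tree$edge[, 1L] == root)
    if (length(kids) != 1L) break
    # unary root: fold its single edge into root.edge and re-root below
    e <- kids
    root.extra <- root.extra + (tree$edge.length[e] %||% 0)
    child <- tree$edge[e, 2L]
    if (child <= ntip) break   # degenerate: single tip left
    tree$edge <- tree$edge[-e, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-e]
    if (!is.null(tree$node.label)) tree$node.label <- tree$node.label[-1L]
    # renumber: old internal numbers shift down by 1 (root removed)
    tree$edge[tree$edge > root] <- tree$edge[tree$edge > root] - 1L
    tree$Nnode <- tree$Nnode - 1L
  }
  tree <- ape::collapse.singles(tree)
  if (root.extra > 0 || !is.null(tree$root.edge))
    tree$root.edge <- (tree$root.edge %||% 0) + root.extra
  tree
}

#' Patristic distance matrix
#'
#' Symmetric matrix of path-length (sum of branch lengths) distances
#' between every pair of tips; zero diagonal. This is the substrate for
#' MPD/MNTD.
#'
#' @param tree a `phylo` object with all branch lengths present.
#' @return Numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("patristic distances require all branch lengths present")
  stats::cophenetic(tree)
}

#' Total branch length of a tree
#'
#' Sum of all branch lengths, including the root edge when one is present
#' with positive length. Equals the root-inclusive PD of the full tip set,
#' and the quantity conserved by summing phylogenetic endemism over cells.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return A single number, in the tree's branch-length units.
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("total_branch_length requires all branch lengths present")
  sum(tree$edge.length) + max(0, tree$root.edge %||% 0)
}

# depth (distance from root) of every node, tips first then internals,
# following ape numbering; root.edge not included
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(1, nrow(tree$edge))
  ord <- reorder(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    depth[ch] <- depth[p] + ord$edge.length[e]
  }
  depth
}

# node ages assuming the tree is ultrametric (max tip depth minus depth)
node_heights_ultra <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Test whether a tree is ultrametric within an absolute tolerance
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tol absolute tolerance on root-to-tip path differences.
#' @return TRUE/FALSE.
#' @export
is_ultrametric_tol <- function(tree, tol = 1e-9) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol
}
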