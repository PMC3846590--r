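#' Date a tree by even-spacing interpolation between landmark ages (bladj)
#'
#' Assigns an age to every internal node given fixed landmark ages for a
#' subset of labeled nodes (the root must be among them; tips are age 0),
#' then recomputes every branch length as the parent-child age difference,
#' yielding an ultrametric tree. Fixed nodes are processed oldest first;
#' each undated node is dated by spacing the chain between its nearest
#' already-dated ancestor A (age tA) and the nearest dated node or tip
#' below it D (age tD) evenly: the k-th of m intervening nodes receives
#' age tA - k (tA - tD)/(m+1). Once dated, a node is never revised, and a
#' landmark age is never altered.
#'
#' When a chain of undated nodes leads to several dated descendants, the
#' chain is spaced toward the oldest of them (ties broken toward the
#' nearest, then the lowest node number). Anchoring on the oldest dated
#' descendant guarantees that every interpolated age stays above every
#' landmark age beneath it, so parent ages always exceed child ages for
#' any landmark set that is itself consistent; remaining chains off the
#' interpolated path are then spaced from the newly dated nodes.
#'
#' @param tree a `phylo` object; internal nodes referenced by the age
#'   table must carry labels. Existing branch lengths are ignored.
#' @param ages named numeric vector of fixed ages (Myr), names matching
#'   internal node labels; see [read_age_table()].
#' @return The tree with branch lengths in Myr (age differences) and an
#'   attribute `node_ages` (numeric, ages of all nodes in ape numbering).
#' @export
bladj_date <- function(tree, ages) {
  stopifnot(inherits(tree, "phylo"))
  ages <- as_age_table(ages)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  labs <- tree$node.label %||% rep("", tree$Nnode)

  idx <- match(names(ages), labs)
  if (anyNA(idx)) {
    warning("age table labels not found in tree (ignored): ",
            paste(names(ages)[is.na(idx)], collapse = ", "))
    ages <- ages[!is.na(idx)]; idx <- idx[!is.na(idx)]
  }
  fixed_nodes <- ntip + idx
  fixed_age <- setNames(unname(ages), fixed_nodes)
  if (!(root %in% fixed_nodes))
    stop("the root node must carry a fixed age (no fixed ancestor for the tree)")

  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  children <- split(tree$edge[, 2L], factor(tree$edge[, 1L], levels = seq_len(nnode)))

  age <- rep(NA_real_, nnode)
  age[seq_len(ntip)] <- 0
  age[fixed_nodes] <- unname(fixed_age)

  # fixed-vs-fixed monotonicity: each fixed node strictly younger than its
  # nearest fixed ancestor
  for (f in setdiff(fixed_nodes, root)) {
    a <- parent[f]
    while (!(a %in% fixed_nodes)) a <- parent[a]
    if (age[f] >= age[a])
      stop("fixed age of node '", labs[f - ntip], "' (", age[f],
           ") is not younger than fixed ancestor '", labs[a - ntip],
           "' (", age[a], ")")
  }

  # dated frontier below `start`: every dated node reachable through
  # undated nodes only; the chain anchor D is the oldest (ties -> nearest,
  # then lowest number). Returns the path start..D.
  dated_anchor_below <- function(start, dated) {
    par <- new.env(parent = emptyenv())
    frontier <- integer(0); fdepth <- integer(0)
    level <- start; depth <- 0L
    while (length(level)) {
      hits <- level[dated[level]]
      frontier <- c(frontier, hits)
      fdepth <- c(fdepth, rep(depth, length(hits)))
      nxt <- integer(0)
      for (v in setdiff(level, hits)) {
        kids <- children[[v]]
        if (length(kids)) {
          for (k in kids) assign(as.character(k), v, envir = par)
          nxt <- c(nxt, kids)
        }
      }
      level <- nxt; depth <- depth + 1L
    }
    if (!length(frontier))
      stop("internal error: undated subtree with no dated node below")
    D <- frontier[order(-age[frontier], fdepth, frontier)][1L]
    path <- D
    while (path[1L] != start)
      path <- c(get(as.character(path[1L]), envir = par), path)
    path
  }

  dated <- !is.na(age)
  queue <- fixed_nodes[order(-age[fixed_nodes], fixed_nodes)]
  while (length(queue)) {
    A <- queue[1L]; queue <- queue[-1L]
    newly <- integer(0)
    for (ch in children[[A]]) {
      if (dated[ch]) next
      path <- dated_anchor_below(ch, dated)      # ch .. D, all but last undated
      D <- path[length(path)]
      m <- length(path) - 1L
      tA <- age[A]; tD <- age[D]
      ks <- seq_len(m)
      age[path[ks]] <- tA - ks * (tA - tD) / (m + 1)
      dated[path[ks]] <- TRUE
      newly <- c(newly, path[ks])
    }
    if (length(newly)) queue <- c(newly, queue)   # finish this subtree first
  }
  if (anyNA(age)) stop("internal error: nodes left undated")

  el <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (any(el < -1e-12)) {                # cannot happen for consistent landmarks
    bad <- which.min(el)
    stop("internal error: negative branch (node ", tree$edge[bad, 1L],
         " -> ", tree$edge[bad, 2L], ") after age interpolation")
  }
  tree$edge.length <- pmax(el, 0)
  attr(tree, "node_ages") <- age
  tree
}
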