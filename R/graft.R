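#' Graft species onto a backbone supertree
#'
#' Phylomatic-style enrichment of a backbone phylogeny: every species in
#' the taxonomy table that is not already a tip is attached as a new tip,
#' as a child of the internal node labeled with its genus if that label
#' exists, otherwise of the node labeled with its family. Multiple
#' attachments at one node form a polytomy; genera are thereby assumed
#' monophyletic. Species whose genus and family labels are both absent
#' from the backbone are recorded as unplaced and skipped with a warning.
#' Newly created edges carry no branch length (absent, not zero): the
#' grafted tree is meant to be dated with [bladj_date()] before any
#' branch-length-based analysis.
#'
#' @param backbone a `phylo` object whose internal nodes may carry genus
#'   and family labels.
#' @param taxa taxonomy data.frame with columns `species`, `genus`,
#'   `family` (see [read_taxonomy()]).
#' @return A list with elements `tree` (the enriched `phylo`) and `report`
#'   (data.frame `species`, `placement` in
#'   `already_present|genus|family|unplaced`, `attached_to`).
#' @export
graft_species <- function(backbone, taxa) {
  stopifnot(inherits(backbone, "phylo"), is.data.frame(taxa))
  need <- c("species", "genus", "family")
  if (!all(need %in% names(taxa)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(taxa$species))
    stop("duplicate species in taxonomy table")

  tree <- backbone
  placement <- character(nrow(taxa))
  attached_to <- character(nrow(taxa))
  for (r in seq_len(nrow(taxa))) {
    sp <- taxa$species[r]
    if (sp %in% tree$tip.label) {
      placement[r] <- "already_present"; attached_to[r] <- sp
      next
    }
    labs <- tree$node.label %||% character(0)
    g <- which(labs == taxa$genus[r])
    f <- which(labs == taxa$family[r])
    if (length(g)) {
      tree <- bind_tip_at_node(tree, length(tree$tip.label) + g[1L], sp)
      placement[r] <- "genus"; attached_to[r] <- taxa$genus[r]
    } else if (length(f)) {
      tree <- bind_tip_at_node(tree, length(tree$tip.label) + f[1L], sp)
      placement[r] <- "family"; attached_to[r] <- taxa$family[r]
    } else {
      placement[r] <- "unplaced"; attached_to[r] <- NA_character_
    }
  }
  report <- data.frame(species = taxa$species, placement = placement,
                       attached_to = attached_to, stringsAsFactors = FALSE)
  n_fam <- sum(placement == "family")
  n_un <- sum(placement == "unplaced")
  if (n_un)
    warning(n_un, " species unplaced (genus and family absent from backbone): ",
            paste(head(report$species[placement == "unplaced"], 5L), collapse = ", "),
            if (n_un > 5L) ", ..." else "")
  if (n_fam)
    message(n_fam, " species placed at family level")
  attr(tree, "order") <- NULL
  list(tree = ape::reorder.phylo(tree, "cladewise"), report = report)
}

# attach one new tip as an additional child of internal node `node`
# (polytomy); new edge has length NA when the tree carries lengths
bind_tip_at_node <- function(tree, node, label) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) stop("can only attach at an internal node")
  if (label %in% tree$tip.label) stop("duplicate tip label: ", label)
  edge <- tree$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L   # internals shift by one
  edge <- rbind(edge, c(node + 1L, ntip + 1L))
  tree$edge <- edge
  tree$tip.label <- c(tree$tip.label, label)
  if (!is.null(tree$edge.length))
    tree$edge.length <- c(tree$edge.length, NA_real_)
  attr(tree, "order") <- NULL
  tree
}
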