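#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that adds strict structural
#' validation: unbalanced parentheses are reported with their character
#' position, tip labels must be unique, and partially missing branch
#' lengths are stored as `NA` (absent), never silently as zero.
#'
#' @param text a Newick string (ending in `;`).
#' @param file alternatively, path to a Newick file; exactly one of
#'   `text`/`file` must be given.
#' @return An object of class `phylo` (see [ape::read.tree()]).
#' @seealso [write_newick()], [prune_to_species()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_balance(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input", call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length)) {
    tree$edge.length[is.nan(tree$edge.length)] <- NA_real_
    if (all(is.na(tree$edge.length))) tree$edge.length <- NULL
  }
  tree
}

# scan for parenthesis balance, reporting the 1-based character position of
# the first offending character (ape's own message does not localize it)
check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    else if (chars[pos] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character position ", pos,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character position ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Write a phylogeny as a Newick string
#'
#' Inverse of [read_newick()]: `read_newick(write_newick(t))` recovers the
#' same topology, labels and branch lengths. Trees whose branch lengths are
#' all absent are written without `:length` fields.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written there.
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  t2 <- tree
  if (!is.null(t2$edge.length) && all(is.na(t2$edge.length)))
    t2$edge.length <- NULL
  txt <- ape::write.tree(t2, digits = digits)
  if (!is.null(file)) {
    write_atomic(file, function(p) writeLines(txt, p))
    return(invisible(txt))
  }
  txt
}

#' Read a landmark age table
#'
#' Two-column delimited text `clade_label<TAB>age` (no header), giving
#' fixed crown ages in Myr for labeled nodes, as consumed by [bladj_date()].
#'
#' @param file path to the table.
#' @return Named numeric vector of ages (Myr).
#' @export
read_age_table <- function(file) {
  d <- read.delim(file, header = FALSE, col.names = c("clade", "age"),
                  stringsAsFactors = FALSE)
  as_age_table(setNames(d$age, d$clade))
}

# validate an age table given as a named numeric vector
as_age_table <- function(ages) {
  if (is.null(names(ages)) || any(!nzchar(names(ages))))
    stop("age table entries must be named by clade label")
  if (anyDuplicated(names(ages)))
    stop("duplicate clade labels in age table: ",
         paste(unique(names(ages)[duplicated(names(ages))]), collapse = ", "))
  ages <- vapply(ages, as.numeric, numeric(1))
  if (any(!is.finite(ages)) || any(ages <= 0))
    stop("ages must be finite and positive")
  ages
}

#' Read a species taxonomy table
#'
#' Delimited text with header `species,genus,family,growth_form`; one row
#' per species, used for supertree grafting ([graft_species()]) and for
#' growth-form species-set selection. `growth_form` must be `freestanding`
#' or `climbing`.
#'
#' @param file path to the table.
#' @param sep field separator.
#' @return A data.frame with the four columns above.
#' @export
read_taxonomy <- function(file, sep = ",") {
  d <- read.csv(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("species", "genus", "family", "growth_form")
  if (!all(need %in% names(d)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  validate_taxonomy(d[need])
}

validate_taxonomy <- function(d) {
  if (anyDuplicated(d$species))
    stop("duplicate species in taxonomy: ",
         paste(unique(d$species[duplicated(d$species)]), collapse = ", "))
  if (any(!nzchar(d$genus)) || any(!nzchar(d$family)))
    stop("genus and family labels must be nonempty")
  bad <- setdiff(unique(d$growth_form), c("freestanding", "climbing"))
  if (length(bad))
    stop("unknown growth_form value(s): ", paste(bad, collapse = ", "))
  d
}
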