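#' Construct an assemblage grid
#'
#' An `assemblage_grid` maps integer grid-cell indices to species presence
#' sets (binary presences, no abundances), together with the cell size,
#' the grid origin, and an optional cell-to-region map. Cell keys are
#' `"i:j"` strings over the integer indices.
#'
#' @param cells named list of character vectors (species per cell), names
#'   of the form `"i:j"`.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, grid origin (x0, y0) in meters.
#' @param regions optional named character vector, region label per cell
#'   key; must cover every cell when present.
#' @return An object of class `assemblage_grid`.
#' @export
assemblage_grid <- function(cells, cell_size, origin = c(0, 0), regions = NULL) {
  stopifnot(is.list(cells), is.numeric(cell_size), cell_size > 0,
            length(origin) == 2L)
  if (length(cells) && (is.null(names(cells)) || any(!nzchar(names(cells)))))
    stop("cells must be named by 'i:j' keys")
  if (any(lengths(cells) == 0L)) stop("every cell must hold at least one species")
  cells <- lapply(cells, function(s) sort(unique(as.character(s))))
  cells <- cells[order(names(cells))]
  if (!is.null(regions)) {
    missing <- setdiff(names(cells), names(regions))
    if (length(missing))
      stop("regions missing for cells: ", paste(head(missing, 5L), collapse = ", "))
    regions <- regions[names(cells)]
  }
  structure(list(cells = cells, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), regions = regions),
            class = "assemblage_grid")
}

#' @export
print.assemblage_grid <- function(x, ...) {
  cat("assemblage_grid:", length(x$cells), "cells,",
      length(grid_species(x)), "species, cell size", x$cell_size, "m\n")
  if (!is.null(x$regions))
    cat("regions:", paste(sort(unique(x$regions)), collapse = ", "), "\n")
  invisible(x)
}

#' Build the "i:j" key for integer cell indices
#' @param i,j integer cell indices (vectorized).
#' @return Character vector of cell keys.
#' @export
cell_key <- function(i, j) paste(i, j, sep = ":")

#' Split cell keys into integer indices
#' @param grid an `assemblage_grid`.
#' @return data.frame with columns `key`, `i`, `j`.
#' @export
cell_indices <- function(grid) {
  keys <- names(grid$cells)
  parts <- matrix(as.integer(unlist(strsplit(keys, ":", fixed = TRUE))),
                  ncol = 2L, byrow = TRUE)
  data.frame(key = keys, i = parts[, 1L], j = parts[, 2L],
             stringsAsFactors = FALSE)
}

#' All species present anywhere in a grid
#' @param grid an `assemblage_grid`.
#' @return Sorted character vector.
#' @export
grid_species <- function(grid) sort(unique(unlist(grid$cells, use.names = FALSE)))

#' Per-cell species richness
#' @param grid an `assemblage_grid`.
#' @return Named integer vector (by cell key).
#' @export
cell_richness <- function(grid) vapply(grid$cells, length, integer(1))

#' Grid point occurrences into cell assemblages
#'
#' Assigns each record at planar coordinates (x, y) in meters to the cell
#' `(floor((x - x0)/cell_size), floor((y - y0)/cell_size))`; cells are
#' half-open `[lo, hi)` on both axes, so a point exactly on a boundary
#' belongs to the higher-indexed cell. Duplicate records of a species in
#' a cell collapse to a single presence. Records with non-finite
#' coordinates are rejected and counted in the `rejects` attribute. When
#' the occurrence table carries a `region` column, each cell receives the
#' majority region label of its records (ties broken toward the
#' lexicographically smallest label).
#'
#' @param occ data.frame with columns `species`, `x`, `y` and optionally
#'   `region` (see [read_occurrences()]).
#' @param cell_size cell edge length in meters.
#' @param origin grid origin (x0, y0); default `c(0, 0)`.
#' @return An `assemblage_grid`; attribute `rejects` counts dropped records.
#' @export
grid_occurrences <- function(occ, cell_size, origin = c(0, 0)) {
  stopifnot(is.data.frame(occ), all(c("species", "x", "y") %in% names(occ)),
            cell_size > 0)
  if (any(!nzchar(occ$species))) stop("species labels must be nonempty")
  ok <- is.finite(occ$x) & is.finite(occ$y)
  n_rejected <- sum(!ok)
  occ <- occ[ok, , drop = FALSE]
  i <- floor((occ$x - origin[1L]) / cell_size)
  j <- floor((occ$y - origin[2L]) / cell_size)
  key <- cell_key(i, j)
  cells <- lapply(split(occ$species, key), function(s) sort(unique(s)))
  regions <- NULL
  if ("region" %in% names(occ) && nrow(occ))
    regions <- vapply(split(occ$region, key), majority_label, character(1))
  g <- assemblage_grid(cells, cell_size, origin, regions)
  attr(g, "rejects") <- n_rejected
  g
}

majority_label <- function(x) {
  tab <- table(x)
  names(tab)[order(-tab, names(tab))][1L]
}

#' Aggregate grid cells by an integer factor
#'
#' Cell `(i, j)` maps to `(floor(i/factor), floor(j/factor))`; species sets
#' are unioned and the cell size multiplied by `factor` (e.g. factor 5
#' takes a 10 km grid to a 50 km grid). The region label of an aggregated
#' cell is carried over when all children agree, otherwise assigned by
#' majority of child cells (ties toward the lexicographically smallest
#' label).
#'
#' @param grid an `assemblage_grid`.
#' @param factor positive integer aggregation factor.
#' @return An `assemblage_grid` at the coarser resolution.
#' @export
aggregate_cells <- function(grid, factor) {
  stopifnot(inherits(grid, "assemblage_grid"),
            factor >= 1, factor == as.integer(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  ix <- cell_indices(grid)
  newkey <- cell_key(ix$i %/% factor, ix$j %/% factor)
  cells <- lapply(split(grid$cells, newkey),
                  function(l) sort(unique(unlist(l, use.names = FALSE))))
  regions <- NULL
  if (!is.null(grid$regions))
    regions <- vapply(split(unname(grid$regions), newkey), majority_label,
                      character(1))
  assemblage_grid(cells, grid$cell_size * factor, grid$origin, regions)
}

#' Retain cells above a richness threshold
#'
#' Keeps exactly the cells holding strictly more than `min_exclusive`
#' species (the default reproduces a "more than 5 species" retention
#' rule used to avoid over-representing sparsely occupied cells).
#'
#' @param grid an `assemblage_grid`.
#' @param min_exclusive integer; cells with richness `> min_exclusive`
#'   are retained.
#' @return The filtered `assemblage_grid`.
#' @export
filter_min_richness <- function(grid, min_exclusive = 5L) {
  stopifnot(inherits(grid, "assemblage_grid"), min_exclusive >= 0)
  keep <- cell_richness(grid) > min_exclusive
  assemblage_grid(grid$cells[keep], grid$cell_size, grid$origin,
                  if (is.null(grid$regions)) NULL else grid$regions[keep])
}

#' Restrict a grid to a species subset
#'
#' Intersects every cell's species set with `keep` (e.g. a growth-form
#' species set); cells left empty are removed.
#'
#' @param grid an `assemblage_grid`.
#' @param keep nonempty character vector of species labels.
#' @return The restricted `assemblage_grid`.
#' @export
restrict_to_species <- function(grid, keep) {
  stopifnot(inherits(grid, "assemblage_grid"), length(keep) >= 1L)
  cells <- lapply(grid$cells, intersect, y = keep)
  nonempty <- lengths(cells) > 0L
  assemblage_grid(cells[nonempty], grid$cell_size, grid$origin,
                  if (is.null(grid$regions)) NULL else grid$regions[nonempty])
}

#' Attach region labels to a grid
#'
#' @param grid an `assemblage_grid`.
#' @param regions named character vector (by `"i:j"` cell key) or
#'   data.frame with columns `cell_i`, `cell_j`, `region`; must cover
#'   every cell.
#' @return The grid with regions attached.
#' @export
set_regions <- function(grid, regions) {
  stopifnot(inherits(grid, "assemblage_grid"))
  if (is.data.frame(regions)) {
    stopifnot(all(c("cell_i", "cell_j", "region") %in% names(regions)))
    regions <- setNames(as.character(regions$region),
                        cell_key(regions$cell_i, regions$cell_j))
  }
  assemblage_grid(grid$cells, grid$cell_size, grid$origin, regions)
}

#' Regional species pools
#'
#' The pool of a region is the union of species sets over the cells
#' labeled with that region; the continental pool (union over all
#' regions) is returned under the name given by `continental`. Region
#' membership is a property of cells, so a species whose range spans
#' several regions belongs to each of their pools.
#'
#' @param grid an `assemblage_grid` with regions set for every cell.
#' @param continental name for the all-regions pool, or NULL to omit it.
#' @return Named list of sorted character vectors.
#' @export
regional_pools <- function(grid, continental = NULL) {
  stopifnot(inherits(grid, "assemblage_grid"))
  if (is.null(grid$regions))
    stop("grid has no region labels; use set_regions() or a region column")
  pools <- lapply(split(grid$cells, unname(grid$regions)),
                  function(l) sort(unique(unlist(l, use.names = FALSE))))
  if (!is.null(continental)) pools[[continental]] <- grid_species(grid)
  pools
}

#' Read an occurrence table
#'
#' Delimited text with header `species,x,y` and optionally `region`;
#' coordinates in meters in a projected planar CRS (any geographic-to-
#' projected transformation is left to pre-processing).
#'
#' @param file path to the table.
#' @param sep field separator.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(file, sep = ",") {
  d <- read.csv(file, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("species", "x", "y") %in% names(d)))
    stop("occurrence table must have columns species,x,y[,region]")
  d
}

#' Convert a grid to a data.frame / write it as delimited text
#'
#' One row per cell: `cell_i,cell_j,region,richness,species` with the
#' species presence set `;`-joined.
#'
#' @param x an `assemblage_grid`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame, one row per cell.
#' @export
as.data.frame.assemblage_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  ix <- cell_indices(x)
  data.frame(cell_i = ix$i, cell_j = ix$j,
             region = if (is.null(x$regions)) NA_character_ else unname(x$regions),
             richness = unname(cell_richness(x)),
             species = vapply(x$cells, paste, character(1), collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.assemblage_grid
#' @param grid an `assemblage_grid`.
#' @param file output path.
#' @export
write_grid <- function(grid, file) {
  d <- as.data.frame(grid)
  write_atomic(file, function(p)
    write.csv(d, p, row.names = FALSE, quote = FALSE))
}

#' Read a grid written by [write_grid()]
#' @param file path to the table.
#' @param cell_size,origin grid geometry (not stored in the table).
#' @return An `assemblage_grid`.
#' @export
read_grid <- function(file, cell_size, origin = c(0, 0)) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  cells <- setNames(strsplit(d$species, ";", fixed = TRUE),
                    cell_key(d$cell_i, d$cell_j))
  regions <- NULL
  if (!all(is.na(d$region)))
    regions <- setNames(as.character(d$region), cell_key(d$cell_i, d$cell_j))
  assemblage_grid(cells, cell_size, origin, regions)
}
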