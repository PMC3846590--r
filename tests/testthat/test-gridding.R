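occ3 <- data.frame(species = c("A", "B", "C"),
                   x = c(12345, 5, 15000), y = c(67890, 5, 100),
                   region = c("north", "south", "south"))

test_that("points map to half-open cells by the floor rule", {
  g <- grid_occurrences(occ3, 10000)
  expect_setequal(names(g$cells), c("1:6", "0:0", "1:0"))
  # boundary point belongs to the higher-indexed cell
  gb <- grid_occurrences(data.frame(species = "A", x = 10000, y = 0), 10000)
  expect_equal(names(gb$cells), "1:0")
  # origin shifts the indexing
  go <- grid_occurrences(data.frame(species = "A", x = 12345, y = 67890),
                         10000, origin = c(10000, 60000))
  expect_equal(names(go$cells), "0:0")
})

test_that("duplicate records collapse; non-finite coordinates are rejected", {
  occ <- data.frame(species = c("A", "A", "A", "B"),
                    x = c(1, 2, NA, Inf), y = c(1, 2, 3, 4))
  g <- grid_occurrences(occ, 10000)
  expect_equal(unname(cell_richness(g)), 1L)
  expect_equal(g$cells[["0:0"]], "A")
  expect_equal(attr(g, "rejects"), 2L)
})

test_that("gridding cell-center points at the same size is idempotent", {
  set.seed(3)
  occ <- data.frame(species = sample(LETTERS[1:8], 60, TRUE),
                    x = runif(60, 0, 5e4), y = runif(60, 0, 5e4))
  g1 <- grid_occurrences(occ, 10000)
  ix <- cell_indices(g1)
  centers <- data.frame(
    species = unlist(g1$cells),
    x = rep((ix$i + 0.5) * 10000, lengths(g1$cells)),
    y = rep((ix$j + 0.5) * 10000, lengths(g1$cells)))
  g2 <- grid_occurrences(centers, 10000)
  expect_identical(g2$cells, g1$cells)
})

test_that("aggregation unions species sets and composes across factors", {
  g <- grid_occurrences(occ3, 10000)
  expect_identical(aggregate_cells(g, 1L), g)
  a <- aggregate_cells(g, 5L)       # (1,6)->(0,1); (0,0),(1,0)->(0,0)
  expect_setequal(names(a$cells), c("0:0", "0:1"))
  expect_setequal(a$cells[["0:0"]], c("B", "C"))
  expect_equal(a$cells[["0:1"]], "A")
  expect_equal(a$cell_size, 50000)

  set.seed(11)
  occ <- data.frame(species = sample(LETTERS, 300, TRUE),
                    x = runif(300, 0, 3e5), y = runif(300, 0, 3e5))
  g0 <- grid_occurrences(occ, 10000)
  expect_identical(aggregate_cells(g0, 6L),
                   aggregate_cells(aggregate_cells(g0, 2L), 3L))
})

test_that("aggregated cells take the majority region, ties lexicographic", {
  cells <- list("0:0" = "A", "1:0" = "B", "0:1" = "C", "1:1" = "D")
  g <- assemblage_grid(cells, 10, regions = c(
    "0:0" = "west", "1:0" = "west", "0:1" = "east", "1:1" = "north"))
  a <- aggregate_cells(g, 2L)
  expect_equal(unname(a$regions), "west")
  g2 <- assemblage_grid(cells[1:2], 10,
                        regions = c("0:0" = "zeta", "1:0" = "alpha"))
  expect_equal(unname(aggregate_cells(g2, 2L)$regions), "alpha")
})

test_that("richness filter is strictly exclusive", {
  cells <- list("0:0" = letters[1:6], "1:0" = letters[1:5], "2:0" = "a")
  g <- assemblage_grid(cells, 10)
  f <- filter_min_richness(g, 5L)
  expect_equal(names(f$cells), "0:0")       # 6 kept, 5 dropped
  expect_setequal(names(filter_min_richness(g, 0L)$cells),
                  c("0:0", "1:0", "2:0"))
})

test_that("species restriction intersects cells and drops emptied ones", {
  g <- assemblage_grid(list("0:0" = c("A", "B"), "1:0" = "A"), 10)
  r <- restrict_to_species(g, c("B", "C"))
  expect_equal(names(r$cells), "0:0")
  expect_equal(r$cells[["0:0"]], "B")
  expect_identical(restrict_to_species(g, c("A", "B")), g)
})

test_that("filtering operations never add species", {
  set.seed(9)
  g <- random_grid(paste0("sp", 1:12), 10)
  for (op in list(function(x) filter_min_richness(x, 3L),
                  function(x) restrict_to_species(x, paste0("sp", 1:6)),
                  function(x) aggregate_cells(x, 3L)))
    expect_true(all(grid_species(op(g)) %in% grid_species(g)))
})

test_that("regional pools are per-region unions; continental is the union", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_grid(paste0("sp", 1:15), 8)
    g <- set_regions(g, setNames(sample(c("r1", "r2", "r3"), 8, TRUE),
                                 names(g$cells)))
    pools <- regional_pools(g, continental = "ALL")
    for (r in setdiff(names(pools), "ALL")) {
      manual <- sort(unique(unlist(g$cells[unname(g$regions) == r])))
      expect_equal(pools[[r]], manual)
    }
    expect_equal(pools$ALL, grid_species(g))
  }
  # disjoint regional floras partition the continental pool
  gd <- assemblage_grid(list("0:0" = c("A", "B"), "5:0" = c("C")), 10,
                        regions = c("0:0" = "w", "5:0" = "e"))
  pd <- regional_pools(gd)
  expect_length(intersect(pd$w, pd$e), 0)
  expect_equal(sum(lengths(pd)), length(grid_species(gd)))
})

test_that("grid tables round-trip through delimited text", {
  g <- grid_occurrences(occ3, 10000)
  f <- tempfile(fileext = ".csv")
  write_grid(g, f)
  g2 <- read_grid(f, 10000)
  expect_identical(g2$cells, g$cells)
  expect_identical(unname(g2$regions), unname(g$regions))
})
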