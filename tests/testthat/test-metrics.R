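tr3 <- read_newick("((A:1,B:1):1,C:2);")
g2 <- assemblage_grid(list("0:0" = c("A", "B"), "1:0" = "C"), 10000)

test_that("PD follows the root-inclusive spanning-subtree convention", {
  expect_equal(faith_pd(tr3, c("A", "B")), 3)
  expect_equal(faith_pd(tr3, c("A", "B", "C")), total_branch_length(tr3))
  expect_equal(faith_pd(tr3, "C"), 2)
  expect_equal(faith_pd(tr3, c("A", "B"), include_root = FALSE), 2)
  expect_equal(faith_pd(tr3, "C", include_root = FALSE), 0)
  expect_error(faith_pd(tr3, character(0)), "nonempty")
  expect_error(faith_pd(tr3, "Z"), "Z")
})

test_that("branch ranges count occupied cells per branch", {
  br <- branch_ranges(tr3, g2)
  # terminal branches restricted to their cell; deep branches span cells
  lab <- function(ch) tr3$tip.label[ch]
  term <- br[br$child <= 3, ]
  expect_equal(term$range[match(c("A", "B", "C"), lab(term$child))],
               c(1L, 1L, 1L))
  expect_equal(br$range[br$child == 5], 1L)   # stem of (A,B)
  for (seed in 1:10) {
    tr <- random_tree(8, seed = seed)
    g <- random_grid(tr$tip.label, 6)
    br <- branch_ranges(tr, g)
    desc <- oracle_edge_descendants(tr)
    manual <- vapply(desc, function(d) {
      sum(vapply(g$cells, function(s)
        length(intersect(s, tr$tip.label[d])) > 0, logical(1)))
    }, numeric(1))
    expect_equal(br$range, as.integer(manual))
  }
})

test_that("PE downweights branches by range and conserves total length", {
  pe <- phylogenetic_endemism(tr3, g2)
  expect_equal(unname(pe), c(3, 2))           # every branch single-cell
  expect_equal(sum(pe), total_branch_length(tr3))

  for (seed in 1:20) {
    tr <- random_tree(sample(4:12, 1), seed = seed)
    g <- random_grid(tr$tip.label, sample(3:10, 1))
    pe <- phylogenetic_endemism(tr, g)
    expect_equal(pe, oracle_pe(tr, g), tolerance = 1e-9)
    expect_equal(sum(pe), total_branch_length(tr), tolerance = 1e-9)
    pd <- vapply(g$cells, function(s) faith_pd(tr, s), numeric(1))
    expect_true(all(pe <= pd + 1e-12))
  }
})

test_that("WE sums inverse ranges and conserves species count", {
  expect_equal(unname(weighted_endemism(g2)), c(2, 1))
  for (seed in 1:10) {
    g <- random_grid(paste0("sp", 1:10), 7)
    we <- weighted_endemism(g)
    expect_equal(we, oracle_we(g), tolerance = 1e-9)
    expect_equal(sum(we), length(grid_species(g)), tolerance = 1e-9)
    expect_true(all(we <= cell_richness(g)))
  }
})

test_that("MPD and MNTD match pair and nearest-neighbor enumeration", {
  D <- patristic_matrix(tr3)
  expect_equal(mpd(D, c("A", "B", "C")), 10 / 3)
  expect_equal(mntd(D, c("A", "B", "C")), 8 / 3)
  expect_equal(mpd(D, c("A", "C")), mntd(D, c("A", "C")))
  expect_equal(mpd(D, c("C", "B", "A")), mpd(D, c("A", "B", "C")))
  expect_error(mpd(D, "A"), "at least 2")
  for (seed in 1:15) {
    tr <- random_tree(10, seed = seed)
    D <- patristic_matrix(tr)
    sp <- sample(tr$tip.label, sample(2:8, 1))
    expect_equal(mpd(D, sp), oracle_mpd(D, sp), tolerance = 1e-9)
    expect_equal(mntd(D, sp), oracle_mntd(D, sp), tolerance = 1e-9)
    expect_lte(mntd(D, sp), mpd(D, sp) + 1e-12)
  }
})

test_that("PD and MPD agree with picante on random fixtures", {
  skip_if_not_installed("picante")
  for (seed in 1:10) {
    tr <- random_tree(12, seed = seed)
    g <- random_grid(tr$tip.label, 6)
    comm <- t(sapply(g$cells, function(s) as.integer(tr$tip.label %in% s)))
    colnames(comm) <- tr$tip.label
    pic_pd <- picante::pd(comm, tr, include.root = TRUE)$PD
    our_pd <- vapply(g$cells, function(s) faith_pd(tr, s), numeric(1))
    keep <- lengths(g$cells) > 1      # picante roots single-species PD differently
    expect_equal(unname(our_pd[keep]), pic_pd[keep], tolerance = 1e-9)
    D <- stats::cophenetic(tr)
    expect_equal(unname(vapply(g$cells[keep], function(s) mpd(D, s), numeric(1))),
                 picante::mpd(comm, D)[keep], tolerance = 1e-9)
    expect_equal(unname(vapply(g$cells[keep], function(s) mntd(D, s), numeric(1))),
                 picante::mntd(comm, D)[keep], tolerance = 1e-9)
  }
})

test_that("adding a species to a cell never decreases PD", {
  for (seed in 1:10) {
    tr <- random_tree(10, seed = seed)
    sp <- sample(tr$tip.label, 4)
    extra <- sample(setdiff(tr$tip.label, sp), 1)
    expect_gte(faith_pd(tr, c(sp, extra)), faith_pd(tr, sp) - 1e-12)
  }
})

test_that("Sorensen dissimilarity follows the shared-fraction formula", {
  expect_equal(sorensen_matrix(list(a = c("A", "B"), b = c("A", "B")))["a", "b"], 0)
  expect_equal(sorensen_matrix(list(a = c("A", "B"), b = c("C")))["a", "b"], 1)
  D <- sorensen_matrix(list(a = c("A", "B"), b = c("B", "C")))
  expect_equal(D["a", "b"], 0.5)
  expect_equal(unname(diag(D)), c(0, 0))
  expect_true(isSymmetric(D))
})

test_that("the metrics table fills pairwise columns only for S >= 2", {
  g <- assemblage_grid(list("0:0" = c("A", "B"), "1:0" = "C"), 10000,
                       regions = c("0:0" = "w", "1:0" = "e"))
  m <- cell_metrics(g, tr3)
  expect_equal(m$S, c(2L, 1L))
  expect_equal(m$PD, c(3, 2))
  expect_equal(m$PE, c(3, 2))
  expect_true(is.na(m$MPD[2]) && is.na(m$MNTD[2]))
  expect_equal(m$MPD[1], 2)
  expect_equal(m$region, c("w", "e"))
  f <- tempfile(fileext = ".csv")
  write_metrics(m, f)
  txt <- readLines(f)
  expect_match(txt[1], "^cell_i,cell_j,region,S,PD,PE,WE,MPD,MNTD,NRI,NTI,class$")
  expect_equal(length(txt), 3L)
})

test_that("richness and PD are tightly correlated on synthetic landscapes", {
  sim <- simulate_scenario(scenario_config(seed = 5))
  grid <- filter_min_richness(sim$grid, 5L)
  m <- cell_metrics(grid, sim$tree)
  expect_gt(cor(m$S, m$PD), 0.9)
})
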