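test_that("null draws preserve richness and never re-use a combination", {
  res <- draw_null_assemblages(LETTERS[1:10], S = 3, max_iter = 50, seed = 4)
  expect_equal(res$n_draws, 50L)
  expect_equal(res$stop_reason, "max_iterations")
  expect_true(all(lengths(res$draws) == 3L))
  keys <- vapply(res$draws, function(d) paste(sort(d), collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("draws exhaust all C(N, S) combinations and stop", {
  res <- draw_null_assemblages(c("A", "B", "C", "D"), S = 2, max_iter = 100,
                               seed = 1)
  expect_equal(res$n_draws, 6L)
  expect_equal(res$stop_reason, "combinations_exhausted")
  keys <- sort(vapply(res$draws, function(d) paste(sort(d), collapse = ","),
                      character(1)))
  expect_equal(keys, sort(apply(combn(c("A", "B", "C", "D"), 2), 2,
                                paste, collapse = ",")))
})

test_that("S equal to the pool is a single degenerate draw; S above errors", {
  res <- draw_null_assemblages(c("A", "B", "C"), S = 3, max_iter = 10, seed = 2)
  expect_equal(res$n_draws, 1L)
  expect_true(res$degenerate)
  expect_setequal(res$draws[[1]], c("A", "B", "C"))
  expect_error(draw_null_assemblages(c("A", "B"), S = 3), "exceeds")
})

test_that("a fixed seed reproduces the draw sequence exactly", {
  a <- draw_null_assemblages(letters[1:12], 4, max_iter = 200, seed = 99)
  b <- draw_null_assemblages(letters[1:12], 4, max_iter = 200, seed = 99)
  expect_identical(a, b)
})

test_that("convergence rule: literal vs relative-range readings", {
  flat <- rep(3.0, 600)
  expect_false(convergence_check(flat, mode = "literal"))
  expect_true(convergence_check(flat, mode = "relative_range"))
  spiky <- c(rep(1, 500), rep(c(0.001, 1.0), 50))
  expect_true(convergence_check(spiky, mode = "literal"))
  # never before min_iter total iterations, whatever the values
  expect_false(convergence_check(rep(3.0, 499), mode = "relative_range"))
  expect_false(convergence_check(c(0.001, rep(1, 150)), mode = "literal"))
})

test_that("standardization matches the exhaustive three-species oracle", {
  # pool {A,B,C} on ((A:1,B:1):1,C:2), S = 2: null MPDs {2, 4, 4}
  expect_equal(standardize_z(2, 10 / 3, sd(c(2, 4, 4))), 1.154701,
               tolerance = 1e-6)
  expect_equal(standardize_z(10 / 3, 10 / 3, 1.2), 0)
  expect_equal(standardize_z(4, 10 / 3, sd(c(2, 4, 4))), -0.5773503,
               tolerance = 1e-6)
  expect_true(is.na(standardize_z(2, 2, 0)))
})

test_that("classification splits sign and strength at the thresholds", {
  expect_equal(classify_structure(c(2.5, 1.2, 0.3, -1.2, -2.5)),
               c("clustered_sig", "clustered_weak", "neutral",
                 "even_weak", "even_sig"))
  expect_equal(classify_structure(c(1.96, -1.0)), c("clustered_sig", "even_weak"))
  expect_true(is.na(classify_structure(NA_real_)))
  expect_error(classify_structure(1, sig_threshold = 1, weak_threshold = 2))
})

test_that("NRI equals the exhaustive z-score when draws exhaust the pool", {
  for (seed in 1:6) {
    set.seed(seed)
    tr <- random_tree(sample(8:12, 1))
    pool <- tr$tip.label
    S <- sample(2:4, 1)
    D <- patristic_matrix(tr)
    # grid: every species somewhere + a few focal cells of richness S
    cells <- c(lapply(1:4, function(i) sample(pool, S)),
               list(pool))
    names(cells) <- cell_key(seq_along(cells) - 1L, 0L)
    g <- assemblage_grid(cells, 1000)
    cfg <- null_config(max_iter = choose(length(pool), S) + 10)
    res <- run_nri_analysis(g, tr, "continental", config = cfg, seed = seed)
    aud <- res$null_audit
    expect_true(all(aud$stop_reason[aud$S == S] == "combinations_exhausted"))
    oracle <- oracle_exhaustive_z(D, pool, S, function(s) mpd(D, s))
    oracle_n <- oracle_exhaustive_z(D, pool, S, function(s) mntd(D, s))
    m <- res$cell_metrics
    for (k in 1:4) {
      expect_equal(m$NRI[k], oracle$z(mpd(D, cells[[k]])), tolerance = 1e-9)
      expect_equal(m$NTI[k], oracle_n$z(mntd(D, cells[[k]])), tolerance = 1e-9)
    }
  }
})

test_that("null distributions are shared across equal-richness cells", {
  set.seed(7)
  tr <- random_tree(15)
  cells <- list("0:0" = sample(tr$tip.label, 5),
                "1:0" = sample(tr$tip.label, 5),
                "2:0" = tr$tip.label)
  g <- assemblage_grid(cells, 1000,
                       regions = setNames(rep("r1", 3), names(cells)))
  res <- run_nri_analysis(g, tr, "continental",
                          config = null_config(max_iter = 300), seed = 1)
  aud <- res$null_audit
  expect_equal(nrow(aud[aud$S == 5 & aud$metric == "MPD", ]), 1L)
  # a single region holding every species reproduces the continental run
  res_r <- run_nri_analysis(g, tr, "regional",
                            config = null_config(max_iter = 300), seed = 1)
  expect_equal(res_r$cell_metrics$NRI, res$cell_metrics$NRI, tolerance = 1e-12)
  expect_equal(res_r$cell_metrics$NTI, res$cell_metrics$NTI, tolerance = 1e-12)
})

test_that("degenerate nulls (S = pool) are flagged, not divided by zero", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  g <- assemblage_grid(list("0:0" = c("A", "B", "C")), 1000)
  res <- run_nri_analysis(g, tr, "continental",
                          config = null_config(max_iter = 10), seed = 1)
  expect_true(is.na(res$cell_metrics$NRI[1]))
  expect_equal(res$cell_metrics$class[1], "neutral_degenerate")
  expect_true(all(res$null_audit$degenerate))
})

test_that("identical seed and config reproduce the analysis bit for bit", {
  sim <- simulate_scenario(scenario_config("neutral", n_species = 40,
                                           n_cells_x = 5, n_cells_y = 5,
                                           seed = 3))
  g <- filter_min_richness(sim$grid, 5L)
  cfg <- null_config(max_iter = 99)
  r1 <- run_nri_analysis(g, sim$tree, "continental", cfg, seed = 11)
  r2 <- run_nri_analysis(g, sim$tree, "continental", cfg, seed = 11)
  expect_identical(r1$cell_metrics, r2$cell_metrics)
  expect_identical(r1$null_audit, r2$null_audit)
})
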