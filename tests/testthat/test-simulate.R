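# The tumor growth simulator.

test_that("configurations are validated", {
  expect_error(sim_config(patterns = c(5, 0), seed = 1), "range")
  expect_error(sim_config(growth = 0, seed = 1), "growth")
  expect_error(sim_config(events = c(gain = 0.9), seed = 1), "sum to 1")
  expect_error(sim_config(), "seed is required")
})

test_that("growth hits the target pattern range from a diploid root", {
  cfg <- sim_config(probes = 4, growth = 0.4, patterns = c(120, 150),
                    seed = 21)
  s <- grow_tree(cfg)
  n <- nrow(s$patterns$counts)
  expect_gte(n, 120L)
  expect_lte(n, 150L)
  dip <- fishsteiner:::pattern_key(rbind(rep(2L, 4)))
  expect_true(dip %in% fishsteiner:::pattern_key(s$patterns$counts))
  expect_identical(unname(s$tree$labels[1, ]), rep(2L, 4))
  expect_identical(sum(s$patterns$multiplicity), nrow(s$tree$labels))
  # trivial range: a single diploid node
  s1 <- grow_tree(sim_config(patterns = c(1, 1), seed = 4))
  expect_identical(nrow(s1$tree$labels), 1L)
})

test_that("identical seed and configuration reproduce the sample exactly", {
  cfg <- sim_config(probes = 6, growth = 0.5, patterns = c(50, 80), seed = 8)
  a <- grow_tree(cfg)
  b <- grow_tree(cfg)
  expect_identical(a$patterns, b$patterns)
  expect_identical(a$tree$labels, b$tree$labels)
  expect_identical(a$events, b$events)
  c <- grow_tree(sim_config(probes = 6, growth = 0.5, patterns = c(50, 80),
                            seed = 9))
  expect_false(identical(a$patterns, c$patterns))
})

test_that("zero-absorbing loss-only growth stays below the diploid state", {
  cfg <- sim_config(probes = 3, growth = 0.6, patterns = c(5, 10),
                    events = c(loss = 1), seed = 12)
  s <- grow_tree(cfg)
  expect_true(all(s$patterns$counts <= 2L))
  expect_true(all(s$patterns$counts >= 0L))
})

test_that("heuristic weight is bounded by the true event count", {
  # with single-gene events only, the lineage tree is a feasible Steiner
  # tree, so any spanning heuristic can do at least as well
  for (seed in 1:10) {
    s <- grow_tree(sim_config(probes = 4, growth = 0.5, patterns = c(10, 25),
                              seed = seed))
    expect_lte(tree_weight(build_mst(s$patterns)), s$event_count)
    expect_lte(tree_weight(msttree(s$patterns)), s$event_count)
  }
})

test_that("benchmarking tabulates best fractions with ties", {
  cfg <- sim_config(probes = 2, growth = 0.5, patterns = c(5, 8), seed = 2)
  b <- benchmark_methods(c("msttree", "mpttree", "exact"), cfg,
                         replicates = 5,
                         config = search_config(restarts = 2))
  expect_s3_class(b, "fish_benchmark")
  exact_frac <- b$best$best_fraction[b$best$method == "exact"]
  expect_identical(exact_frac, 1)  # the optimum is always among the best
  expect_true(all(b$best$best_fraction >= 0 & b$best$best_fraction <= 1))
  expect_identical(nrow(b$results), 15L)
})
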