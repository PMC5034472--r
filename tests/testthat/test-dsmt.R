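# Generalized duplication metric and the DSMT pipeline.

chrom4 <- c(P1 = "chr1", P2 = "chr1", P3 = "chr2", P4 = "chr2")

test_that("duplication_distance picks the cheapest event script", {
  m <- event_model()
  dd <- duplication_distance(c(2, 2, 2, 2), c(4, 4, 4, 4), m, chrom4)
  expect_identical(dd$cost, 1L)
  expect_identical(dd$script, "wgd")
  dd2 <- duplication_distance(c(2, 2, 2, 2), c(4, 4, 2, 2), m, chrom4)
  expect_identical(dd2$cost, 1L)
  expect_identical(dd2$script, "dup:chr1")
  dd3 <- duplication_distance(c(2, 2), c(2, 3), event_model(chromosomal = FALSE))
  expect_identical(dd3$cost, 1L)
  expect_identical(dd3$script, character(0))
  expect_error(duplication_distance(c(2, 2), c(4, 4), event_model()),
               "chromosome map")
})

test_that("duplication_distance never exceeds the L1 distance", {
  set.seed(43)
  m <- event_model()
  for (i in 1:200) {
    a <- sample(0:8, 4, TRUE); b <- sample(0:8, 4, TRUE)
    dd <- duplication_distance(a, b, m, chrom4)
    expect_lte(dd$cost, l1_dist(a, b))
    expect_identical(as.numeric(dd$cost),
                     brute_dup_cost(a, b, chrom4))
  }
})

test_that("duplication branches are detected along the rooted tree", {
  t <- steiner_tree(rbind(c(2, 2, 2, 2), c(4, 4, 4, 5)), rbind(c(1L, 2L)),
                    c(TRUE, TRUE))
  br <- detect_duplication_branches(t, event_model(), chrom4)
  expect_identical(nrow(br), 1L)  # L1 = 9, WGD + one gain = 2
  expect_identical(br$cost, 2L)
  expect_identical(br$script, "wgd")
  t2 <- steiner_tree(rbind(c(2, 2), c(3, 2)), rbind(c(1L, 2L)), c(TRUE, TRUE))
  expect_identical(nrow(detect_duplication_branches(
    t2, event_model(chromosomal = FALSE))), 0L)
  t3 <- build_mst(rbind(c(2, 2, 2, 2), c(2, 3, 2, 2), c(2, 3, 3, 2)))
  expect_identical(nrow(detect_duplication_branches(t3, event_model(),
                                                    chrom4)), 0L)
})

test_that("split/rebuild/reassemble composes subtree optima", {
  x <- fish_patterns(rbind(c(2, 2, 2, 2), c(4, 4, 4, 4), c(4, 4, 4, 5)),
                     chromosomes = chrom4)
  t <- dsmttree(x, event_model(), method = "mst")
  expect_identical(attr(t, "generalized_weight"), 2L)  # one WGD + one gain
  # no near-doubling patterns: same result as the plain heuristic
  y <- fish_patterns(rbind(c(2, 2, 2, 2), c(2, 3, 2, 2), c(2, 3, 3, 2)),
                     chromosomes = chrom4)
  ty <- dsmttree(y, event_model(), method = "mst")
  expect_identical(attr(ty, "generalized_weight"),
                   as.integer(tree_weight(msttree(y))))
  single <- dsmttree(fish_patterns(rbind(c(2, 2, 2, 2)), chromosomes = chrom4))
  expect_identical(attr(single, "generalized_weight"), 0L)
})

test_that("dsmttree never exceeds the RSMT weight of the same inputs", {
  set.seed(47)
  ev <- c(gain = 0.42, loss = 0.42, chromosomal = 0.12, wgd = 0.04)
  for (i in 1:10) {
    cfg <- sim_config(probes = 4, growth = 0.5, patterns = c(15, 30),
                      events = ev, seed = 100 + i)
    x <- grow_tree(cfg)$patterns
    t <- dsmttree(x, event_model(), cfg$chromosomes, method = "mst")
    expect_lte(attr(t, "generalized_weight"), tree_weight(msttree(x)))
    # every observed pattern survives the pipeline
    expect_true(all(fishsteiner:::pattern_key(x$counts) %in%
                      fishsteiner:::pattern_key(t$labels)))
    # reassembled branches carry their scripts
    br <- attr(t, "dup_branches")
    if (!is.null(br) && nrow(br) > 0) expect_true(all(nzchar(br$script)))
  }
})
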