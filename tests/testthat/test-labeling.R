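# Internal-node labeling: ranges, assignment, lifting, candidate selection.

quartet_topo <- function() {
  # rooted on the central edge: cherries (1,2) and (3,4), root node 7
  mpt_topology(rbind(c(1, 5), c(2, 5), c(5, 7), c(7, 6), c(3, 6), c(4, 6)), 4)
}

test_that("bottom-up ranges reproduce the Farris intervals", {
  x <- matrix(c(0, 2, 8, 10), ncol = 1)
  rng <- bottom_up_ranges(quartet_topo(), x, root = 7)
  expect_identical(c(rng$lo[5, ], rng$hi[5, ]), c(0L, 2L))
  expect_identical(c(rng$lo[6, ], rng$hi[6, ]), c(8L, 10L))
  expect_identical(c(rng$lo[7, ], rng$hi[7, ]), c(2L, 8L))
  # identical leaves: degenerate intervals
  y <- matrix(rep(4, 4), ncol = 1)
  rng2 <- bottom_up_ranges(quartet_topo(), y, root = 7)
  expect_true(all(rng2$lo == 4L & rng2$hi == 4L))
  # 3-leaf tree: the internal interval is the median point
  t3 <- mpt_topology(rbind(c(1, 4), c(2, 4), c(3, 4)), 3)
  rng3 <- bottom_up_ranges(t3, matrix(c(0, 4, 2), ncol = 1), root = 4)
  expect_identical(c(rng3$lo[4, ], rng3$hi[4, ]), c(2L, 2L))
})

test_that("top-down assignment clamps to the intervals at optimal weight", {
  x <- matrix(c(0, 2, 8, 10), ncol = 1)
  topo <- quartet_topo()
  for (rv in c(2L, 5L, 8L)) {
    tr <- top_down_assign(topo, x, 7, rv)
    expect_identical(tree_weight(tr), 10L)
  }
  # cherry internals clamp to 2 and 8 whatever the root value in [2,8]
  tr <- top_down_assign(topo, x, 7, 5L)
  expect_identical(unname(tr$labels[5:7, 1]), c(2L, 8L, 5L))
  expect_error(top_down_assign(topo, x, 7, 20L), "outside")
})

test_that("leaf lifting is detected exactly", {
  x <- rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2), c(3, 3, 3))
  fit <- mpt_search(x, search_config(restarts = 2))
  # the middle patterns can label their parents at no extra cost
  expect_true(any(vapply(1:4, can_lift, logical(1), mpt = fit, x = x)))
  expect_true(can_lift(fit, 2, x))
  # the 3-pattern star forces the Steiner median: nothing lifts
  y <- rbind(c(0, 0), c(4, 2), c(2, 6))
  fit3 <- mpt_search(y, search_config(restarts = 1))
  expect_false(any(vapply(1:3, can_lift, logical(1), mpt = fit3, x = y)))
  expect_error(can_lift(fit3, 9, y), "unknown leaf")
})

test_that("derive_rsmt preserves weight and minimises Steiner nodes", {
  x <- rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2), c(3, 3, 3))
  cand <- derive_rsmt(mpt_search(x, search_config(restarts = 2)), x)
  expect_identical(cand$weight, 3L)
  expect_identical(cand$steiner_nodes, 0L)
  expect_identical(nrow(cand$tree$labels), 4L)  # chain of the four inputs
  y <- rbind(c(0, 0), c(4, 2), c(2, 6))
  cand3 <- derive_rsmt(mpt_search(y, search_config(restarts = 1)), y)
  expect_identical(cand3$weight, 10L)
  expect_identical(cand3$steiner_nodes, 1L)
  single <- derive_rsmt(mpt_search(rbind(c(2, 2))), rbind(c(2, 2)))
  expect_identical(single$weight, 0L)
  set.seed(17)
  for (i in 1:25) {
    P <- rand_patterns(sample(4:6, 1), sample(1:3, 1), 6)
    fit <- mpt_search(P, search_config(restarts = 2))
    cand <- derive_rsmt(fit, P)
    # labeling and contraction never change the parsimony weight
    expect_identical(as.numeric(cand$weight), as.numeric(fit$score))
    expect_lte(cand$steiner_nodes, nrow(P) - 2L)
    expect_gte(cand$weight, exact_rsmt(P)$weight)
    # every input pattern labels a node of the candidate
    expect_true(all(fishsteiner:::pattern_key(P) %in%
                      fishsteiner:::pattern_key(cand$tree$labels)))
  }
})
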