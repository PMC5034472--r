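# MST construction and iterative median insertion.

test_that("build_mst finds a minimum spanning tree deterministically", {
  t <- build_mst(rbind(c(0, 0), c(1, 0), c(5, 0)))
  expect_identical(tree_weight(t), 5L)
  single <- build_mst(rbind(c(2, 2)))
  expect_identical(tree_weight(single), 0L)
  expect_identical(nrow(single$labels), 1L)
  square <- build_mst(rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2)))
  expect_identical(tree_weight(square), 6L)
  set.seed(3)
  for (i in 1:20) {
    P <- rand_patterns(sample(2:5, 1), 2, 4)
    expect_identical(as.numeric(tree_weight(build_mst(P))),
                     brute_mst_weight(P))
    # determinism
    expect_identical(build_mst(P)$edges, build_mst(P)$edges)
  }
})

test_that("enumerate_triples lists one instance per center/neighbor pair", {
  path <- build_mst(rbind(c(0, 0), c(4, 2), c(2, 6)))
  tri <- enumerate_triples(path)
  expect_identical(length(tri$center), 1L)
  expect_identical(unname(tri$median[1, ]), c(2L, 2L))
  expect_identical(tri$gain, 2L)  # edge pair weight 12 vs star weight 10
  expect_true(tri$required)
  star <- steiner_tree(rbind(c(2, 2), c(0, 0), c(4, 2), c(2, 6)),
                       rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                       c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(length(enumerate_triples(star)$center), 3L)  # C(3,2)
})

test_that("iterate_insert reaches the local optimum with monotone weight", {
  t <- iterate_insert(build_mst(rbind(c(0, 0), c(4, 2), c(2, 6))))
  expect_identical(tree_weight(t), 10L)
  expect_identical(sum(!t$observed), 1L)
  expect_identical(unname(t$labels[!t$observed, ]), c(2L, 2L))
  # no improving median: the tree is already at a local optimum
  t2 <- iterate_insert(build_mst(rbind(c(1, 1), c(3, 1), c(1, 3))))
  expect_identical(tree_weight(t2), 4L)
  expect_identical(nrow(t2$labels), 3L)
  # idempotence at the fixed point
  t3 <- iterate_insert(t)
  expect_identical(tree_weight(t3), tree_weight(t))
  expect_identical(nrow(t3$labels), nrow(t$labels))
})

test_that("msttree keeps observed patterns, never beats the exact optimum", {
  x <- rbind(c(0, 0), c(4, 2), c(2, 6))
  t <- msttree(x)
  expect_identical(tree_weight(t), 10L)
  expect_identical(tree_weight(msttree(rbind(c(2, 2, 2, 2)))), 0L)
  expect_identical(tree_weight(msttree(rbind(c(1, 1), c(3, 1), c(1, 3)))), 4L)
  set.seed(19)
  for (i in 1:30) {
    P <- rand_patterns(sample(3:6, 1), sample(1:3, 1), 6)
    t <- msttree(P)
    w <- attr(t, "weights")
    expect_true(all(diff(w) <= 0))  # monotone across iterations
    expect_lte(tree_weight(t), tree_weight(build_mst(P)))
    expect_gte(tree_weight(t), exact_rsmt(P)$weight)
    # every observed pattern survives
    expect_true(all(fishsteiner:::pattern_key(P) %in%
                      fishsteiner:::pattern_key(t$labels)))
  }
})
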