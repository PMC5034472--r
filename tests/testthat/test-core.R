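# Core metric, median and tree bookkeeping.

test_that("the rectilinear distance behaves as a metric on count patterns", {
  expect_identical(l1_dist(c(2, 2, 2, 2), c(2, 2, 2, 2)), 0L)
  expect_identical(l1_dist(c(2, 1, 4, 2), c(2, 2, 2, 2)), 3L)
  expect_identical(l1_dist(c(0, 5), c(3, 1)), 7L)
  expect_error(l1_dist(c(1, 2), c(1, 2, 3)), "different numbers of probes")
  set.seed(42)
  for (i in 1:50) {
    d <- sample(1:4, 1)
    a <- sample(0:10, d, TRUE); b <- sample(0:10, d, TRUE)
    cc <- sample(0:10, d, TRUE)
    expect_gte(l1_dist(a, b), 0)
    expect_identical(l1_dist(a, b), l1_dist(b, a))
    expect_identical(l1_dist(a, b) == 0L, identical(as.integer(a),
                                                    as.integer(b)))
    expect_lte(l1_dist(a, cc), l1_dist(a, b) + l1_dist(b, cc))
  }
})

test_that("median3 gives the optimal Steiner point for a triple", {
  expect_identical(median3(c(2, 2), c(2, 2), c(2, 2)), c(2L, 2L))
  expect_identical(median3(c(0, 0), c(4, 2), c(2, 6)), c(2L, 2L))
  # the median of a triple can coincide with an input: no new node needed
  expect_identical(median3(c(1, 1), c(3, 1), c(1, 3)), c(1L, 1L))
  set.seed(7)
  for (i in 1:200) {
    d <- sample(1:4, 1)
    a <- sample(0:10, d, TRUE); b <- sample(0:10, d, TRUE)
    cc <- sample(0:10, d, TRUE)
    m <- median3(a, b, cc)
    star <- l1_dist(m, a) + l1_dist(m, b) + l1_dist(m, cc)
    ex <- exhaustive_median(a, b, cc)
    expect_identical(star, as.integer(ex$weight))
    expect_identical(m, ex$pattern)
    expect_identical(star, as.integer(sum(pmax(a, b, cc) - pmin(a, b, cc))))
  }
})

test_that("a Steiner node is required exactly when the median is new", {
  expect_true(is_steiner_required(c(0, 0), c(4, 2), c(2, 6)))
  expect_false(is_steiner_required(c(1, 1), c(3, 1), c(1, 3)))
  expect_false(is_steiner_required(c(5), c(5), c(7)))
})

test_that("tree weight sums the branch lengths", {
  t1 <- steiner_tree(rbind(c(2, 2), c(3, 4)), rbind(c(1L, 2L)),
                     c(TRUE, TRUE))
  expect_identical(tree_weight(t1), 3L)
  star <- steiner_tree(rbind(c(2, 2), c(0, 0), c(4, 2), c(2, 6)),
                       rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                       c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(tree_weight(star), 10L)
  path <- steiner_tree(matrix(0:2, ncol = 1), rbind(c(1L, 2L), c(2L, 3L)),
                       rep(TRUE, 3))
  expect_identical(tree_weight(path), 2L)
  expect_identical(count_steiner_nodes(star,
                                       rbind(c(0, 0), c(4, 2), c(2, 6))), 1L)
  expect_identical(count_steiner_nodes(path, matrix(0:2, ncol = 1)), 0L)
})

test_that("contracting trivial edges merges equal labels, keeps weight", {
  chain <- steiner_tree(rbind(c(2, 2), c(2, 2), c(4, 2)),
                        rbind(c(1L, 2L), c(2L, 3L)),
                        c(TRUE, FALSE, TRUE))
  out <- contract_trivial_edges(chain)
  expect_identical(nrow(out$labels), 2L)
  expect_identical(tree_weight(out), tree_weight(chain))
  expect_true(all(out$observed))
  # idempotent on trees without trivial edges
  expect_identical(contract_trivial_edges(out)$labels, out$labels)
  set.seed(11)
  for (i in 1:25) {
    P <- rand_patterns(5, 2, 3)
    t <- build_mst(P)
    # graft a duplicate-labeled unobserved node onto node 1
    t2 <- steiner_tree(rbind(t$labels, t$labels[1, ]),
                       rbind(t$edges, c(1L, nrow(t$labels) + 1L)),
                       c(t$observed, FALSE))
    out <- contract_trivial_edges(t2)
    expect_identical(tree_weight(out), tree_weight(t2))
    expect_lte(nrow(out$labels), nrow(t2$labels))
    expect_false(any(fishsteiner:::edge_lengths_l1(out) == 0L))
  }
})

test_that("pattern sets merge duplicates and validate input", {
  x <- fish_patterns(rbind(c(1, 2), c(1, 2), c(3, 4)), c(3L, 2L, 1L))
  expect_identical(nrow(x$counts), 2L)
  expect_identical(x$multiplicity, c(5L, 1L))
  expect_error(fish_patterns(rbind(c(-1, 2))), "non-negative")
  expect_error(fish_patterns(rbind(c(1, 2)), multiplicity = 0L), "positive")
  expect_error(fish_patterns(rbind(c(1, 2)),
                             chromosomes = c(P1 = "chr1")), "misses")
})
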