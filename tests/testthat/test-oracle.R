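# Exact small-instance solver.

test_that("exact_rsmt solves the worked instances optimally", {
  expect_identical(exact_rsmt(rbind(c(0, 0), c(4, 2), c(2, 6)))$weight, 10L)
  expect_identical(
    exact_rsmt(rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2)))$weight, 6L)
  res <- exact_rsmt(rbind(c(0, 0), c(2, 0), c(1, 3)))
  expect_identical(res$weight, 5L)  # via Steiner point (1,0); MST weighs 6
  key <- fishsteiner:::pattern_key(res$tree$labels)
  expect_true(fishsteiner:::pattern_key(rbind(c(1L, 0L))) %in% key)
})

test_that("exact trees only carry high-degree Steiner nodes", {
  set.seed(29)
  for (i in 1:20) {
    P <- rand_patterns(sample(3:5, 1), 2, 5)
    res <- exact_rsmt(P)
    t <- res$tree
    expect_identical(tree_weight(t), res$weight)
    deg <- tabulate(t$edges, nbins = nrow(t$labels))
    expect_true(all(deg[!t$observed] >= 3))
  }
})

test_that("for three terminals the optimum is the median star bound", {
  set.seed(37)
  for (i in 1:30) {
    P <- rand_patterns(3, sample(1:3, 1), 8)
    expect_identical(as.integer(exact_rsmt(P)$weight),
                     as.integer(sum(apply(P, 2, max) - apply(P, 2, min))))
  }
})

test_that("the Hanan-grid optimum matches unrestricted brute force", {
  set.seed(41)
  for (i in 1:20) {
    P <- rand_patterns(sample(3:4, 1), 2, 3)
    expect_identical(as.numeric(exact_rsmt(P)$weight), brute_rsmt_weight(P))
  }
})

test_that("the solver refuses oversized instances with a diagnostic", {
  big <- cbind(0:19, 0)
  expect_error(exact_rsmt(big), "20 terminals")
  wide <- rand_patterns(8, 5, 50)
  expect_error(exact_rsmt(wide, max_vertices = 100), "Hanan grid")
})
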