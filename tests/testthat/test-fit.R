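# The fitter-style front end.

test_that("rsmt() returns a classed fit with methods", {
  x <- rbind(c(0, 0), c(4, 2), c(2, 6))
  fit <- rsmt(x, method = "mst")
  expect_s3_class(fit, "rsmt")
  expect_identical(fit$weight, 10L)
  expect_identical(fit$steiner_nodes, 1L)
  expect_output(print(fit), "tree weight: 10")
  expect_output(print(summary(fit)), "weight 10")
  fit2 <- rsmt(x, method = "mpt", config = search_config(restarts = 1))
  expect_identical(fit2$weight, 10L)
  fit3 <- rsmt(x, method = "exact")
  expect_identical(fit3$weight, 10L)
})

test_that("dsmt() reports generalized weight and duplication branches", {
  chrom <- c(P1 = "chr1", P2 = "chr1", P3 = "chr2", P4 = "chr2")
  x <- fish_patterns(rbind(c(2, 2, 2, 2), c(4, 4, 4, 4), c(4, 4, 4, 5)),
                     chromosomes = chrom)
  fit <- dsmt(x)
  expect_s3_class(fit, "dsmt")
  expect_identical(fit$generalized_weight, 2L)
  expect_output(print(fit), "generalized")
})

test_that("the three methods respect the optimality sandwich", {
  set.seed(53)
  for (i in 1:10) {
    P <- rand_patterns(sample(4:6, 1), 2, 6)
    w_exact <- rsmt(P, method = "exact")$weight
    w_mpt <- rsmt(P, method = "mpt",
                  config = search_config(restarts = 2))$weight
    w_mst <- rsmt(P, method = "mst")$weight
    expect_lte(w_exact, w_mpt)
    expect_lte(w_exact, w_mst)
    expect_lte(w_mst, tree_weight(build_mst(P)))
  }
})
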