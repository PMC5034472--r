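# Wagner parsimony scoring and topology search.

test_that("wagner_score matches brute-force labeling minima", {
  quartet <- mpt_topology(rbind(c(1, 5), c(2, 5), c(5, 6), c(3, 6), c(4, 6)),
                          4)
  expect_identical(
    wagner_score(quartet, matrix(c(0, 2, 8, 10), ncol = 1))$weight, 10)
  expect_identical(
    wagner_score(quartet, matrix(c(3, 3, 3, 3), ncol = 1))$weight, 0)
  triple <- mpt_topology(rbind(c(1, 4), c(2, 4), c(3, 4)), 3)
  expect_identical(wagner_score(triple, matrix(c(0, 4, 2), ncol = 1))$weight,
                   4)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    d <- sample(1:3, 1)
    P <- rand_patterns(n, d, 6)
    topos <- all_topologies(n)
    topo <- topos[[sample(length(topos), 1)]]
    expect_identical(wagner_score(mpt_topology(topo, n), P)$weight,
                     brute_label_weight(topo, n, P, 6))
  }
})

test_that("wagner_score is invariant to the rooting of the sweep", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    P <- rand_patterns(n, 2, 5)
    topos <- all_topologies(n)
    topo <- mpt_topology(topos[[sample(length(topos), 1)]], n)
    w1 <- wagner_score(topo, P, root = 1L)$weight
    for (r in sample(seq_len(n), 2))
      expect_identical(wagner_score(topo, P, root = r)$weight, w1)
  }
})

test_that("wagner_score rejects malformed topologies", {
  bad <- mpt_topology(rbind(c(1, 4), c(2, 4), c(3, 4), c(4, 5)), 4)
  expect_error(wagner_score(bad, rand_patterns(4, 2, 3)), "binary")
})

test_that("stepwise addition attains the quartet optimum", {
  x <- rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2), c(3, 3, 3))
  topo <- stepwise_addition(x)
  expect_identical(wagner_score(topo, x)$weight, 3)
  # 3 patterns: the unique unrooted topology
  t3 <- stepwise_addition(rbind(c(0, 0), c(4, 2), c(2, 6)))
  expect_identical(nrow(t3$edges), 3L)
})

test_that("mpt_search finds the global optimum on small instances", {
  fit <- mpt_search(rbind(c(0, 0), c(4, 2), c(2, 6)),
                    search_config(restarts = 1))
  expect_identical(fit$score, 10)
  x <- rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2), c(3, 3, 3))
  for (seed in 1:3)
    expect_identical(mpt_search(x, search_config(restarts = 2,
                                                 seed = seed))$score, 3)
  two <- mpt_search(rbind(c(0, 3), c(2, 0)), search_config())
  expect_identical(two$score, 5L)
  # hill-climbed score never exceeds the plain stepwise score
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    P <- rand_patterns(n, 2, 6)
    sw <- wagner_score(stepwise_addition(P), P)$weight
    fit <- mpt_search(P, search_config(restarts = 1))
    expect_lte(fit$score, sw)
  }
})

test_that("NNI and SPR searches agree with exhaustive topology search", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(4:5, 1)
    P <- rand_patterns(n, 2, 5)
    best <- min(vapply(all_topologies(n), function(ed)
      wagner_score(mpt_topology(ed, n), P)$weight, numeric(1)))
    expect_identical(mpt_search(P, search_config(restarts = 4))$score, best)
    expect_identical(
      mpt_search(P, search_config(restarts = 4,
                                  neighborhood = "spr"))$score, best)
  }
})

test_that("parsimony scoring agrees with an independent Sankoff scorer", {
  skip_if_not_installed("phangorn")
  skip_if_not_installed("ape")
  set.seed(13)
  n <- 6
  P <- rand_patterns(n, 3, 5)
  fit <- mpt_search(P, search_config(restarts = 2))
  # same topology handed to phangorn with an ordered-character cost matrix
  nwk <- local({
    adj <- lapply(seq_len(max(fit$edges)), function(i) integer(0))
    for (e in seq_len(nrow(fit$edges))) {
      adj[[fit$edges[e, 1]]] <- c(adj[[fit$edges[e, 1]]], fit$edges[e, 2])
      adj[[fit$edges[e, 2]]] <- c(adj[[fit$edges[e, 2]]], fit$edges[e, 1])
    }
    rec <- function(v, from) {
      kids <- setdiff(adj[[v]], from)
      if (!length(kids)) return(paste0("t", v))
      paste0("(", paste(vapply(kids, rec, character(1), from = v),
                        collapse = ","), ")")
    }
    paste0(rec(n + 1, NA), ";")
  })
  tree <- ape::read.tree(text = nwk)
  states <- 0:5
  cost <- abs(outer(states, states, `-`))
  dimnames(cost) <- list(states, states)
  dat <- phangorn::phyDat(matrix(as.character(P), nrow = n,
                                 dimnames = list(paste0("t", 1:n), NULL)),
                          type = "USER", levels = as.character(states))
  sk <- phangorn::parsimony(tree, dat, method = "sankoff", cost = cost)
  expect_identical(as.numeric(fit$score), as.numeric(sk))
})
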