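# Independent brute-force oracles used to validate the algorithms on small
# instances. These deliberately avoid the package's own code paths: spanning
# trees are enumerated, labelings are enumerated per probe, and Steiner
# points are enumerated over the bounding box.

# distinct random patterns, counts in 0..maxv
rand_patterns <- function(n, d, maxv) {
  repeat {
    P <- matrix(sample(0:maxv, n * d, replace = TRUE), n, d)
    if (!anyDuplicated(apply(P, 1, paste, collapse = ","))) return(P)
  }
}

l1_matrix <- function(P, Q = P) {
  out <- matrix(0, nrow(P), nrow(Q))
  for (j in seq_len(ncol(P)))
    out <- out + abs(outer(P[, j], Q[, j], `-`))
  out
}

# Prim's algorithm on a distance matrix (independent of the package MST)
prim_weight <- function(D) {
  n <- nrow(D)
  if (n == 1) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  w <- 0
  for (i in seq_len(n - 1)) {
    v <- which(!intree)[which.min(best[!intree])]
    w <- w + best[v]
    intree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  w
}

# minimum spanning tree weight by enumerating every spanning tree (tiny n)
brute_mst_weight <- function(P) {
  n <- nrow(P)
  D <- l1_matrix(P)
  pairs <- t(combn(n, 2))
  best <- Inf
  for (pick in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    ed <- pairs[pick, , drop = FALSE]
    comp <- seq_len(n)
    for (e in seq_len(nrow(ed))) {
      a <- comp[ed[e, 1]]; b <- comp[ed[e, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1)
      best <- min(best, sum(D[ed]))
  }
  best
}

# minimum weight over all integer labelings of the internal nodes of a tree
# topology with labeled tips; per-probe enumeration (the metric separates)
brute_label_weight <- function(edges, n_tips, P, maxv = max(P)) {
  N <- max(edges)
  internal <- setdiff(seq_len(N), seq_len(n_tips))
  total <- 0
  for (j in seq_len(ncol(P))) {
    if (length(internal) == 0) {
      total <- total + sum(abs(P[edges[, 1], j] - P[edges[, 2], j]))
      next
    }
    grid <- as.matrix(expand.grid(rep(list(0:maxv), length(internal))))
    lab <- matrix(0L, nrow(grid), N)
    lab[, seq_len(n_tips)] <- matrix(P[, j], nrow(grid), n_tips, byrow = TRUE)
    lab[, internal] <- grid
    w <- rowSums(abs(lab[, edges[, 1], drop = FALSE] -
                       lab[, edges[, 2], drop = FALSE]))
    total <- total + min(w)
  }
  total
}

# all unrooted binary topologies on n tips (sequential edge insertion)
all_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- list(rbind(c(1L, n + 1L), c(2L, n + 1L), c(3L, n + 1L)))
  if (n == 3) return(base)
  topos <- base
  for (tip in 4:n) {
    newint <- n + tip - 2L
    out <- list()
    for (ed in topos) {
      for (e in seq_len(nrow(ed))) {
        cand <- ed
        v <- cand[e, 2]
        cand[e, 2] <- newint
        cand <- rbind(cand, c(newint, v), c(newint, tip))
        out[[length(out) + 1L]] <- cand
      }
    }
    topos <- out
  }
  topos
}

# optimal RSMT weight for tiny instances: minimum over subsets of candidate
# Steiner points (bounding-box integer points) of the MST over terminals
# plus chosen points; valid for up to 4 terminals (<= t-2 Steiner points)
brute_rsmt_weight <- function(P) {
  n <- nrow(P)
  stopifnot(n <= 4)
  box <- as.matrix(expand.grid(lapply(seq_len(ncol(P)), function(j)
    seq(min(P[, j]), max(P[, j])))))
  best <- prim_weight(l1_matrix(P))
  max_extra <- max(0, n - 2)
  for (k in seq_len(max_extra)) {
    for (pick in combn(nrow(box), k, simplify = FALSE)) {
      Q <- rbind(P, box[pick, , drop = FALSE])
      best <- min(best, prim_weight(l1_matrix(Q)))
    }
  }
  best
}

# independent generalized-distance oracle: enumerate wgd x chromosome-subset
# doubling combinations via expand.grid
brute_dup_cost <- function(parent, child, chromosomes, wgd = TRUE,
                           chromosomal = TRUE) {
  chroms <- if (chromosomal) unique(unname(chromosomes)) else character(0)
  flags <- expand.grid(c(list(wgd = if (wgd) c(FALSE, TRUE) else FALSE),
                         stats::setNames(rep(list(c(FALSE, TRUE)),
                                             length(chroms)), chroms)))
  best <- Inf
  for (i in seq_len(nrow(flags))) {
    fac <- rep(1, length(parent))
    nev <- 0
    if (isTRUE(flags$wgd[i])) {
      fac <- fac * 2
      nev <- nev + 1
    }
    for (ch in chroms) {
      if (isTRUE(flags[[ch]][i])) {
        fac[unname(chromosomes) == ch] <- fac[unname(chromosomes) == ch] * 2
        nev <- nev + 1
      }
    }
    best <- min(best, nev + sum(abs(parent * fac - child)))
  }
  best
}
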