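# MST-based RSMT heuristic: build the L1 minimum spanning tree, then
# iteratively insert median Steiner nodes, cheapest inference score first,
# until no median instance improves the weight.

#' Minimum spanning tree over the observed patterns
#'
#' Kruskal's algorithm on the complete L1 graph of the distinct patterns.
#' Ties are broken deterministically: edges are ordered by length, then by
#' the lexicographically sorted endpoint patterns, so identical inputs give
#' identical trees.
#'
#' @param x a `fish_patterns` object or pattern matrix.
#' @return a `steiner_tree` whose nodes are exactly the input patterns.
#' @examples
#' build_mst(rbind(c(0, 0), c(1, 0), c(5, 0)))
#' @export
build_mst <- function(x) {
  x <- as_fish_patterns(x)
  P <- x$counts
  n <- nrow(P)
  if (n == 1L)
    return(steiner_tree(P, matrix(integer(0), ncol = 2), TRUE,
                        x$multiplicity, colnames(P)))
  D <- as.matrix(stats::dist(P, method = "manhattan"))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[idx]
  key <- pattern_key(P)
  k1 <- pmin(key[idx[, 1]], key[idx[, 2]])
  k2 <- pmax(key[idx[, 1]], key[idx[, 2]])
  ord <- order(w, k1, k2)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ed <- matrix(integer(0), ncol = 2)
  for (e in ord) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      ed <- rbind(ed, as.integer(idx[e, ]))
      if (nrow(ed) == n - 1L) break
    }
  }
  steiner_tree(P, ed, rep(TRUE, n), x$multiplicity, colnames(P))
}

#' Enumerate median instances of a tree
#'
#' One instance per (center node, unordered pair of its neighbors), each
#' annotated with the median pattern, the local gain (weight of the two
#' center-incident edges minus the weight of the 3-star at the median) and
#' whether the median is a new (Steiner) state for the triple.
#'
#' @param t a fully labeled `steiner_tree`.
#' @return a list with vectors `center`, `n1`, `n2`, `gain`, `required` and a
#'   matrix `median` (one row per instance).
#' @export
enumerate_triples <- function(t) {
  n <- nrow(t$labels)
  adj <- adjacency_list(n, t$edges)
  center <- integer(0); n1 <- integer(0); n2 <- integer(0)
  for (v in seq_len(n)) {
    nb <- sort(adj[[v]])
    if (length(nb) >= 2L) {
      pr <- utils::combn(nb, 2)
      center <- c(center, rep(v, ncol(pr)))
      n1 <- c(n1, pr[1, ])
      n2 <- c(n2, pr[2, ])
    }
  }
  if (!length(center))
    return(list(center = integer(0), n1 = integer(0), n2 = integer(0),
                median = matrix(integer(0), ncol = ncol(t$labels)),
                gain = integer(0), required = logical(0)))
  A <- t$labels[n1, , drop = FALSE]
  B <- t$labels[center, , drop = FALSE]
  C <- t$labels[n2, , drop = FALSE]
  M <- A + B + C - pmax(A, B, C) - pmin(A, B, C)
  star <- rowSums(pmax(A, B, C) - pmin(A, B, C))
  gain <- rowSums(abs(A - B)) + rowSums(abs(B - C)) - star
  required <- rowSums(M != A) > 0 & rowSums(M != B) > 0 & rowSums(M != C) > 0
  list(center = center, n1 = n1, n2 = n2, median = M,
       gain = as.integer(gain), required = required)
}

# Steiner count per node: number of enumerated triples containing the node
# whose median differs from all three members.
steiner_counts <- function(t, tri) {
  n <- nrow(t$labels)
  members <- c(tri$center[tri$required], tri$n1[tri$required],
               tri$n2[tri$required])
  tabulate(members, nbins = n)
}

# remove Steiner nodes of degree <= 2 that do not shorten the tree
splice_steiner <- function(t) {
  repeat {
    n <- nrow(t$labels)
    adj <- adjacency_list(n, t$edges)
    deg <- lengths(adj)
    drop <- NA_integer_
    new_edge <- NULL
    for (v in seq_len(n)) {
      if (t$observed[v] || deg[v] > 2L) next
      if (deg[v] <= 1L) {
        drop <- v
        break
      }
      p <- adj[[v]][1]; q <- adj[[v]][2]
      if (l1_dist(t$labels[p, ], t$labels[q, ]) ==
          l1_dist(t$labels[p, ], t$labels[v, ]) +
          l1_dist(t$labels[v, ], t$labels[q, ])) {
        drop <- v
        new_edge <- c(p, q)
        break
      }
    }
    if (is.na(drop)) return(t)
    keepE <- t$edges[, 1] != drop & t$edges[, 2] != drop
    ed <- t$edges[keepE, , drop = FALSE]
    if (!is.null(new_edge)) ed <- rbind(ed, new_edge)
    keep <- setdiff(seq_len(n), drop)
    remap <- match(seq_len(n), keep)
    ed <- cbind(remap[ed[, 1]], remap[ed[, 2]])
    t <- steiner_tree(t$labels[keep, , drop = FALSE], ed, t$observed[keep],
                      t$multiplicity[keep], t$probes,
                      if (is.na(t$root)) NA_integer_ else remap[t$root])
  }
}

#' Iterative median insertion
#'
#' Starting from a labeled tree (typically the MST), repeatedly inserts the
#' median of the candidate triple with positive local gain and minimum
#' inference score (sum of the Steiner counts of the triple's three nodes),
#' replacing the two center-incident edges by the 3-star at the median.
#' After each insertion, unobserved nodes of degree at most two that do not
#' shorten the tree are spliced out. Stops at a local optimum; the weight is
#' non-increasing across iterations.
#'
#' Tie-breaks (in order): larger local gain, lexicographically smallest
#' median pattern, then smallest (center, neighbor) indices — all runs are
#' reproducible without a seed.
#'
#' @param t a fully labeled `steiner_tree` containing the observed patterns.
#' @return a `steiner_tree`; attribute `"weights"` records the weight after
#'   each iteration (starting weight first).
#' @export
iterate_insert <- function(t) {
  weights <- tree_weight(t)
  repeat {
    tri <- enumerate_triples(t)
    cand <- which(tri$gain > 0L)
    if (!length(cand)) break
    sc <- steiner_counts(t, tri)
    score <- sc[tri$center[cand]] + sc[tri$n1[cand]] + sc[tri$n2[cand]]
    mkey <- pattern_key(tri$median[cand, , drop = FALSE])
    pick <- cand[order(score, -tri$gain[cand], mkey, tri$center[cand],
                       tri$n1[cand], tri$n2[cand])[1]]
    t <- insert_median(t, tri$n1[pick], tri$center[pick], tri$n2[pick],
                       tri$median[pick, ])
    t <- splice_steiner(t)
    w <- tree_weight(t)
    if (w > weights[length(weights)])
      stop("internal error: weight increased during median insertion")
    weights <- c(weights, w)
  }
  attr(t, "weights") <- weights
  t
}

# replace edges (u,v),(v,w) by the 3-star at the median; reuse an existing
# endpoint when the median coincides with one of the three labels
insert_median <- function(t, u, v, w, med) {
  med <- as.integer(med)
  n <- nrow(t$labels)
  if (identical(med, as.integer(t$labels[u, ]))) {
    s <- u
  } else if (identical(med, as.integer(t$labels[w, ]))) {
    s <- w
  } else if (identical(med, as.integer(t$labels[v, ]))) {
    s <- v
  } else {
    t$labels <- rbind(t$labels, med)
    rownames(t$labels) <- NULL
    t$observed <- c(t$observed, FALSE)
    t$multiplicity <- c(t$multiplicity, NA_integer_)
    s <- n + 1L
  }
  ed <- t$edges
  is_uv <- (ed[, 1] == u & ed[, 2] == v) | (ed[, 1] == v & ed[, 2] == u)
  is_vw <- (ed[, 1] == v & ed[, 2] == w) | (ed[, 1] == w & ed[, 2] == v)
  ed <- ed[!(is_uv | is_vw), , drop = FALSE]
  for (other in c(u, v, w)) {
    if (other != s) ed <- rbind(ed, c(s, other))
  }
  steiner_tree(t$labels, ed, t$observed, t$multiplicity, t$probes, t$root)
}

#' MST-based RSMT heuristic (MSTtree)
#'
#' Builds the L1 minimum spanning tree of the observed patterns and refines
#' it by [iterate_insert()]. The final weight never exceeds the MST weight
#' and every observed pattern remains in the tree.
#'
#' @param x a `fish_patterns` object or pattern matrix.
#' @return a `steiner_tree` with iteration weights in attribute `"weights"`.
#' @examples
#' t <- msttree(rbind(c(0, 0), c(4, 2), c(2, 6)))
#' tree_weight(t)  # 10
#' @export
msttree <- function(x) {
  x <- as_fish_patterns(x)
  iterate_insert(build_mst(x))
}
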