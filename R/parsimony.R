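# Maximum parsimony tree (MPT) construction under the rectilinear metric:
# exact Wagner (ordered-character) scoring by interval dynamic programming,
# greedy stepwise addition and hill-climbing search. This replaces an
# external parsimony program with a self-contained integer-state search.

#' Search configuration for the parsimony tree search
#'
#' @param restarts number of random-addition restarts (>= 1). The first
#'   restart always uses the input order, so a single restart is fully
#'   deterministic.
#' @param neighborhood `"nni"` (default) or `"spr"` hill climbing.
#' @param seed integer seed controlling the random addition orders.
#' @param max_rounds cap on hill-climbing rounds per restart.
#' @return an object of class `search_config`.
#' @export
search_config <- function(restarts = 10L, neighborhood = c("nni", "spr"),
                          seed = 1L, max_rounds = 200L) {
  restarts <- as.integer(restarts)
  if (is.na(restarts) || restarts < 1L) stop("restarts must be >= 1")
  structure(list(restarts = restarts,
                 neighborhood = match.arg(neighborhood),
                 seed = as.integer(seed),
                 max_rounds = as.integer(max_rounds)),
            class = "search_config")
}

#' Unrooted tree topologies over pattern leaves
#'
#' Leaves are numbered `1..n` (rows of the pattern set); internal nodes are
#' `n+1..2n-2`. For `n < 3` the topology degenerates to a single node or a
#' single edge.
#'
#' @param edges two-column integer matrix.
#' @param n_tips number of leaves.
#' @return an object of class `mpt_topology`.
#' @export
mpt_topology <- function(edges, n_tips) {
  edges <- matrix(as.integer(edges), ncol = 2)
  structure(list(edges = edges, n_tips = as.integer(n_tips)),
            class = "mpt_topology")
}

topo_n_nodes <- function(topo) {
  if (nrow(topo$edges) == 0L) topo$n_tips else max(topo$edges, topo$n_tips)
}

check_binary <- function(topo) {
  n <- topo$n_tips
  if (n < 3L) return(invisible(TRUE))
  N <- topo_n_nodes(topo)
  if (N != 2L * n - 2L || nrow(topo$edges) != 2L * n - 3L)
    stop("topology is not an unrooted binary tree on ", n, " leaves")
  deg <- tabulate(topo$edges, nbins = N)
  if (any(deg[seq_len(n)] != 1L) || any(deg[(n + 1L):N] != 3L))
    stop("topology is not an unrooted binary tree on ", n, " leaves")
  invisible(TRUE)
}

# full-node label matrix (tips filled, internals zero) and tip flags;
# accepts a raw matrix so duplicate leaf labels are allowed here
topo_labels <- function(topo, x) {
  P <- if (inherits(x, "fish_patterns")) x$counts else as.matrix(x)
  storage.mode(P) <- "integer"
  if (nrow(P) != topo$n_tips) stop("pattern count does not match tip count")
  N <- topo_n_nodes(topo)
  labels <- matrix(0L, N, ncol(P))
  labels[seq_len(topo$n_tips), ] <- P
  colnames(labels) <- colnames(P)
  list(labels = labels,
       has = c(rep(TRUE, topo$n_tips), rep(FALSE, N - topo$n_tips)))
}

#' Wagner parsimony score of a leaf-labeled topology
#'
#' Per-probe bottom-up interval dynamic programming on an arbitrary rooting:
#' a leaf's interval is its own count, an internal node combines its
#' children's intervals (intersection at no cost, else the gap interval at a
#' cost equal to the gap). The total over probes equals the minimum of
#' [tree_weight()] over all integer labelings of the internal nodes; it does
#' not depend on the rooting chosen for the sweep.
#'
#' @param topo an `mpt_topology` (unrooted binary) with `n >= 2` tips.
#' @param x the leaf patterns (`fish_patterns` or matrix), row i labeling
#'   tip i.
#' @param root node index used to root the sweep (default: tip 1).
#' @return list with `weight` and per-node interval matrices `lo`, `hi`
#'   (plus the DP bookkeeping `m`, `parent`, `order`, `root`).
#' @examples
#' quartet <- mpt_topology(rbind(c(1, 5), c(2, 5), c(5, 6), c(3, 6), c(4, 6)), 4)
#' wagner_score(quartet, matrix(c(0, 2, 8, 10), ncol = 1))$weight  # 10
#' @export
wagner_score <- function(topo, x, root = 1L) {
  check_binary(topo)
  if (topo$n_tips == 1L)
    return(list(weight = 0, lo = as_fish_patterns(x)$counts,
                hi = as_fish_patterns(x)$counts))
  tl <- topo_labels(topo, x)
  up <- wagner_up_cpp(topo$edges, tl$labels, tl$has, root)
  up$root <- root
  up
}

# unchecked variant used on rooted / pruned topologies
wagner_up_tree <- function(edges, labels, has, root) {
  wagner_up_cpp(matrix(as.integer(edges), ncol = 2), labels, has,
                as.integer(root))
}

#' Greedy stepwise addition
#'
#' Builds an unrooted binary topology by inserting the leaves one at a time,
#' in the given order, at the edge minimising the Wagner score of the grown
#' tree. Deterministic for a fixed order.
#'
#' @param x the patterns (`fish_patterns` or matrix).
#' @param order insertion order of the leaves (default: input order).
#' @return an `mpt_topology`.
#' @export
stepwise_addition <- function(x, order = NULL) {
  P <- as_fish_patterns(x)$counts
  n <- nrow(P)
  if (is.null(order)) order <- seq_len(n)
  order <- as.integer(order)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("order must be a permutation of the leaves")
  if (n == 1L) return(mpt_topology(matrix(integer(0), ncol = 2), 1L))
  if (n == 2L) return(mpt_topology(rbind(c(1L, 2L)), 2L))
  mpt_topology(stepwise_cpp(P, order), n)
}

# SPR hill climbing (small instances): prune every subtree and regraft on
# every edge of the remaining tree, keeping the best strict improvement.
spr_climb <- function(edges, P, n, max_rounds) {
  N <- 2L * n - 2L
  labels <- matrix(0L, N, ncol(P))
  labels[seq_len(n), ] <- P
  has <- c(rep(TRUE, n), rep(FALSE, N - n))
  score <- function(ed) score_topology_cpp(ed, labels, has, 1L)
  cur <- score(edges)
  rounds <- 0L
  repeat {
    if (rounds >= max_rounds) break
    best <- cur
    best_ed <- NULL
    m <- nrow(edges)
    for (e in seq_len(m)) {
      for (side in 1:2) {
        v <- edges[e, side]      # root of the pruned subtree
        u <- edges[e, 3 - side]  # attachment point left behind
        if (u <= n) next         # u must be internal (it gets spliced out)
        rest <- edges[-e, , drop = FALSE]
        comp <- tree_components(N, rest)
        inU <- comp == comp[u]
        nb <- c(rest[rest[, 1] == u & inU[rest[, 2]], 2],
                rest[rest[, 2] == u & inU[rest[, 1]], 1])
        nb <- setdiff(nb, v)
        if (length(nb) != 2L) next
        keep <- !((rest[, 1] == u) | (rest[, 2] == u))
        base <- rbind(rest[keep, , drop = FALSE], nb)
        for (f in seq_len(nrow(base))) {
          p <- base[f, 1]; q <- base[f, 2]
          if (comp[p] != comp[u] || comp[q] != comp[u]) next
          cand <- base
          cand[f, ] <- c(p, u)
          cand <- rbind(cand, c(u, q), c(u, v))
          sc <- score(cand)
          if (sc < best) {
            best <- sc
            best_ed <- cand
          }
        }
      }
    }
    if (is.null(best_ed)) break
    edges <- best_ed
    cur <- best
    rounds <- rounds + 1L
  }
  list(edges = edges, score = cur)
}

#' Parsimony tree search
#'
#' Best topology over random-addition restarts, each refined by NNI (default)
#' or SPR hill climbing until no neighboring topology improves the Wagner
#' score. Reproducible given the configuration seed.
#'
#' @param x the patterns (`fish_patterns` or matrix).
#' @param config a [search_config()].
#' @return an object of class `mpt`: the best `mpt_topology` plus `score`,
#'   the per-restart scores and the configuration.
#' @examples
#' fit <- mpt_search(rbind(c(0, 0), c(4, 2), c(2, 6)), search_config(restarts = 1))
#' fit$score  # 10
#' @export
mpt_search <- function(x, config = search_config()) {
  x <- as_fish_patterns(x)
  P <- x$counts
  n <- nrow(P)
  if (n < 3L) {
    topo <- stepwise_addition(x)
    w <- if (n == 2L) l1_dist(P[1, ], P[2, ]) else 0
    return(structure(list(edges = topo$edges, n_tips = n, score = w,
                          restart_scores = w, config = config),
                     class = c("mpt", "mpt_topology")))
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  best <- NULL
  scores <- numeric(0)
  for (r in seq_len(config$restarts)) {
    ord <- if (r == 1L) seq_len(n) else sample(n)
    topo <- stepwise_addition(x, ord)
    if (config$neighborhood == "nni") {
      res <- nni_cpp(topo$edges, P, n, config$max_rounds)
    } else {
      res <- spr_climb(topo$edges, P, n, config$max_rounds)
    }
    scores <- c(scores, res$score)
    if (is.null(best) || res$score < best$score) {
      best <- list(edges = matrix(as.integer(res$edges), ncol = 2),
                   score = res$score)
    }
  }
  structure(list(edges = best$edges, n_tips = n, score = best$score,
                 restart_scores = scores, config = config),
            class = c("mpt", "mpt_topology"))
}

#' @export
print.mpt <- function(x, ...) {
  cat(sprintf("maximum parsimony topology: %d leaves, weight %d (%d restart%s)\n",
              x$n_tips, as.integer(x$score), length(x$restart_scores),
              if (length(x$restart_scores) == 1) "" else "s"))
  invisible(x)
}
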