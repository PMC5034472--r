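# Turning a maximum parsimony topology into an RSMT: bottom-up interval
# ranges, top-down label assignment, leaf lifting, trivial-edge contraction
# and selection of the candidate with fewest Steiner nodes at unchanged
# weight.

#' Bottom-up label ranges of a rooted topology
#'
#' Per-probe Farris intervals: the set of internal labels that keep the tree
#' weight minimal, propagated from the leaves to the chosen root.
#'
#' @param topo an `mpt_topology` (or any tree edge list with labeled tips).
#' @param x the leaf patterns.
#' @param root the root node index.
#' @return list with interval matrices `lo` and `hi` (rows = nodes), the DP
#'   cost matrix `m`, the `parent` vector and the sweep `order`.
#' @export
bottom_up_ranges <- function(topo, x, root) {
  tl <- topo_labels(topo, x)
  up <- wagner_up_tree(topo$edges, tl$labels, tl$has, root)
  up$root <- as.integer(root)
  up
}

#' Top-down assignment of internal labels
#'
#' Given the bottom-up ranges and a value for the root, each internal node
#' takes (per probe) the value in its interval closest to its parent's
#' assigned value. When the root value lies in the root interval the
#' resulting tree attains the Wagner score; with a forced root value outside
#' the interval (the leaf-lifting construction) it attains the minimal
#' weight among labelings with that root value.
#'
#' @param topo an `mpt_topology`.
#' @param x the leaf patterns.
#' @param root the root node index.
#' @param root_value integer pattern assigned to the root.
#' @param ranges optional precomputed [bottom_up_ranges()].
#' @param strict error when `root_value` lies outside the root interval
#'   (default TRUE); the lifting construction disables this.
#' @return a fully labeled `steiner_tree` (rooted at `root`).
#' @export
top_down_assign <- function(topo, x, root, root_value, ranges = NULL,
                            strict = TRUE) {
  x <- as_fish_patterns(x)
  if (is.null(ranges)) ranges <- bottom_up_ranges(topo, x, root)
  root_value <- as.integer(root_value)
  if (strict && (any(root_value < ranges$lo[root, ]) ||
                 any(root_value > ranges$hi[root, ])))
    stop("root value lies outside the root interval")
  N <- topo_n_nodes(topo)
  d <- ncol(x$counts)
  labels <- matrix(NA_integer_, N, d)
  n <- topo$n_tips
  labels[seq_len(n), ] <- x$counts
  labels[root, ] <- root_value
  for (v in rev(ranges$order)) {  # parents before children
    if (v == root || v <= n) next
    p <- ranges$parent[v]
    labels[v, ] <- pmin(pmax(labels[p, ], ranges$lo[v, ]), ranges$hi[v, ])
  }
  present <- ranges$order  # pruned topologies leave unreached nodes behind
  remap <- match(seq_len(N), sort(present))
  ed <- topo$edges
  ed <- cbind(remap[ed[, 1]], remap[ed[, 2]])
  keep <- sort(present)
  key_in <- pattern_key(x$counts)
  lab <- labels[keep, , drop = FALSE]
  observed <- pattern_key(lab) %in% key_in
  mult <- x$multiplicity[match(pattern_key(lab), key_in)]
  colnames(lab) <- colnames(x$counts)
  steiner_tree(lab, ed, observed, mult, colnames(x$counts), remap[root])
}

# prune one leaf; returns edges without that leaf and its former parent
prune_leaf <- function(topo, leaf) {
  ed <- topo$edges
  hit <- ed[, 1] == leaf | ed[, 2] == leaf
  if (!any(hit)) stop("leaf ", leaf, " not found in topology")
  parent <- setdiff(as.integer(ed[hit, ]), leaf)
  list(edges = ed[!hit, , drop = FALSE], parent = parent)
}

#' Can a leaf be lifted to its parent?
#'
#' A leaf lifts when its pattern can label its former parent without
#' increasing the tree weight: deleting the leaf, rooting the remainder at
#' the parent and forcing the root label to the leaf's pattern scores
#' exactly the MPT weight.
#'
#' @param mpt a scored `mpt` / `mpt_topology` over the inputs.
#' @param leaf tip index (1..n).
#' @param x the leaf patterns.
#' @return logical.
#' @export
can_lift <- function(mpt, leaf, x) {
  x <- as_fish_patterns(x)
  n <- mpt$n_tips
  leaf <- as.integer(leaf)
  if (is.na(leaf) || leaf < 1L || leaf > n) stop("unknown leaf id: ", leaf)
  if (n <= 2L) return(TRUE)
  W <- wagner_score(mpt_topology(mpt$edges, n), x)$weight
  forced_lift_weight(mpt, leaf, x) == W
}

# weight of the pruned tree rooted at the former parent with the root label
# forced to the leaf's pattern
forced_lift_weight <- function(mpt, leaf, x) {
  pr <- prune_leaf(mpt, leaf)
  tl <- topo_labels(mpt_topology(mpt$edges, mpt$n_tips), x)
  up <- wagner_up_tree(pr$edges, tl$labels, tl$has, pr$parent)
  kids <- which(!is.na(up$parent) & up$parent == pr$parent)
  v <- as_fish_patterns(x)$counts[leaf, ]
  w <- 0
  for (c in kids) {
    w <- w + sum(up$m[c, ]) +
      sum(pmax(0L, up$lo[c, ] - v, v - up$hi[c, ]))
  }
  w
}

# build the lifted candidate for one leaf (assumes can_lift is TRUE)
lift_candidate <- function(mpt, leaf, x) {
  x <- as_fish_patterns(x)
  pr <- prune_leaf(mpt, leaf)
  topo <- mpt_topology(pr$edges, mpt$n_tips)
  tl <- topo_labels(mpt_topology(mpt$edges, mpt$n_tips), x)
  up <- wagner_up_tree(pr$edges, tl$labels, tl$has, pr$parent)
  up$root <- pr$parent
  top_down_assign(topo, x, pr$parent, x$counts[leaf, ], ranges = up,
                  strict = FALSE)
}

#' Derive an RSMT from a maximum parsimony topology
#'
#' For every leaf that can be lifted, builds a rooted candidate (the lifted
#' parent takes the leaf's label), assigns internal labels top-down and
#' contracts trivial edges; one fallback candidate roots the unmodified
#' topology at an internal node with the root label chosen inside the root
#' interval as close as possible to the diploid pattern (2,...,2). The
#' candidate with the fewest Steiner nodes (ties: weight, then provenance)
#' is returned; its weight always equals the parsimony score of the input
#' topology.
#'
#' @param mpt an `mpt` (from [mpt_search()]) or `mpt_topology`.
#' @param x the leaf patterns.
#' @return an object of class `candidate_tree`: list with `tree`
#'   (a `steiner_tree`), `weight`, `steiner_nodes`, `provenance` and
#'   `mpt_weight`.
#' @examples
#' x <- rbind(c(2, 2, 2), c(3, 2, 2), c(3, 3, 2), c(3, 3, 3))
#' fit <- mpt_search(x, search_config(restarts = 1))
#' derive_rsmt(fit, x)$weight  # 3, with 0 Steiner nodes
#' @export
derive_rsmt <- function(mpt, x) {
  x <- as_fish_patterns(x)
  n <- mpt$n_tips
  if (is.null(n)) stop("mpt must be an mpt_topology")
  if (n == 1L) {
    t <- steiner_tree(x$counts, matrix(integer(0), ncol = 2), TRUE,
                      x$multiplicity)
    return(structure(list(tree = t, weight = 0L, steiner_nodes = 0L,
                          provenance = "trivial", mpt_weight = 0L),
                     class = "candidate_tree"))
  }
  if (n == 2L) {
    t <- steiner_tree(x$counts, rbind(c(1L, 2L)), c(TRUE, TRUE),
                      x$multiplicity)
    w <- tree_weight(t)
    return(structure(list(tree = t, weight = w, steiner_nodes = 0L,
                          provenance = "trivial", mpt_weight = w),
                     class = "candidate_tree"))
  }
  topo <- mpt_topology(mpt$edges, n)
  W <- wagner_score(topo, x)$weight
  cands <- list()
  for (leaf in seq_len(n)) {
    if (forced_lift_weight(mpt, leaf, x) != W) next
    tr <- contract_trivial_edges(lift_candidate(mpt, leaf, x))
    cands[[length(cands) + 1L]] <- list(
      tree = tr, weight = tree_weight(tr),
      steiner_nodes = count_steiner_nodes(tr, x),
      provenance = sprintf("lift:%04d", leaf))
  }
  # fallback: root at the internal node next to tip 1, bias toward diploid
  root <- setdiff(as.integer(topo$edges[topo$edges[, 1] == 1L |
                                          topo$edges[, 2] == 1L, ]), 1L)[1]
  rng <- bottom_up_ranges(topo, x, root)
  rv <- pmin(pmax(2L, rng$lo[root, ]), rng$hi[root, ])
  tr <- contract_trivial_edges(
    top_down_assign(topo, x, root, rv, ranges = rng))
  cands[[length(cands) + 1L]] <- list(
    tree = tr, weight = tree_weight(tr),
    steiner_nodes = count_steiner_nodes(tr, x),
    provenance = "root:diploid")
  wts <- vapply(cands, `[[`, numeric(1), "weight")
  if (any(wts != W))
    stop("internal error: candidate weight differs from the parsimony score")
  st <- vapply(cands, `[[`, integer(1), "steiner_nodes")
  prov <- vapply(cands, `[[`, character(1), "provenance")
  pick <- order(st, wts, prov)[1]
  out <- cands[[pick]]
  out$mpt_weight <- W
  structure(out, class = "candidate_tree")
}

#' @export
print.candidate_tree <- function(x, ...) {
  cat(sprintf("RSMT candidate (%s): weight %d, %d Steiner node%s\n",
              x$provenance, as.integer(x$weight), x$steiner_nodes,
              if (x$steiner_nodes == 1) "" else "s"))
  invisible(x)
}

#' MPT-based RSMT heuristic (MPTtree)
#'
#' Runs the parsimony tree search and derives the RSMT by internal-node
#' labeling and trivial-edge contraction.
#'
#' @param x a `fish_patterns` object or pattern matrix.
#' @param config a [search_config()].
#' @return a `candidate_tree` (see [derive_rsmt()]).
#' @export
mpttree <- function(x, config = search_config()) {
  x <- as_fish_patterns(x)
  derive_rsmt(mpt_search(x, config), x)
}
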