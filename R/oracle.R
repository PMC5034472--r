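# Exact RSMT solver for small instances: optimal Steiner points lie on the
# Hanan grid (the Cartesian product of the terminals' per-probe values), on
# which the Dreyfus-Wagner subset dynamic program finds the optimum.

#' Exact rectilinear Steiner minimum tree (small instances)
#'
#' Solves RSMT to optimality on the Hanan grid of the input patterns via the
#' Dreyfus-Wagner dynamic program (exponential in the number of terminals).
#' Instances beyond the limits are refused with a size diagnostic — the
#' solver never silently approximates.
#'
#' @param x the observed `fish_patterns` (or pattern matrix).
#' @param max_terminals refuse instances with more distinct patterns.
#' @param max_vertices refuse instances whose Hanan grid is larger.
#' @return list with `weight` (the optimal tree weight) and `tree` (a
#'   `steiner_tree` whose unobserved nodes all have degree >= 3).
#' @examples
#' exact_rsmt(rbind(c(0, 0), c(4, 2), c(2, 6)))$weight  # 10
#' @export
exact_rsmt <- function(x, max_terminals = 8L, max_vertices = 5000L) {
  x <- as_fish_patterns(x)
  P <- x$counts
  n <- nrow(P)
  if (n > max_terminals)
    stop(sprintf("instance has %d terminals, above the limit of %d", n,
                 max_terminals))
  gridsize <- prod(apply(P, 2, function(col) length(unique(col))))
  if (gridsize > max_vertices)
    stop(sprintf("Hanan grid has %d vertices, above the limit of %d",
                 gridsize, max_vertices))
  if (n == 1L) {
    t <- steiner_tree(P, matrix(integer(0), ncol = 2), TRUE, x$multiplicity)
    return(list(weight = 0L, tree = t))
  }
  res <- exact_steiner_cpp(P, as.integer(max_vertices))
  labels <- res$coords
  colnames(labels) <- colnames(P)
  nn <- nrow(labels)
  observed <- seq_len(nn) %in% res$term_index
  t <- steiner_tree(labels, res$edges, observed,
                    replace(rep(NA_integer_, nn), res$term_index,
                            x$multiplicity),
                    colnames(P))
  t <- prune_splice_nonterminals(t)
  w <- tree_weight(t)
  if (w != res$weight)
    stop("internal error: reconstructed tree weight differs from the DP")
  list(weight = as.integer(res$weight), tree = t)
}

# drop degree-1 unobserved vertices and splice degree-2 unobserved vertices;
# in the rectilinear grid the spliced edge length equals the L1 distance, so
# the weight is preserved exactly
prune_splice_nonterminals <- function(t) {
  repeat {
    n <- nrow(t$labels)
    deg <- tabulate(t$edges, nbins = n)
    victim <- which(!t$observed & deg <= 2L)
    if (!length(victim)) return(t)
    v <- victim[1]
    keepE <- t$edges[, 1] != v & t$edges[, 2] != v
    nb <- setdiff(as.integer(t$edges[!keepE, ]), v)
    ed <- t$edges[keepE, , drop = FALSE]
    if (length(nb) == 2L) ed <- rbind(ed, nb)
    keep <- setdiff(seq_len(n), v)
    remap <- match(seq_len(n), keep)
    ed <- cbind(remap[ed[, 1]], remap[ed[, 2]])
    t <- steiner_tree(t$labels[keep, , drop = FALSE], ed, t$observed[keep],
                      t$multiplicity[keep], t$probes)
  }
}
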