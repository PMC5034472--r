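# Fitter-style front end: rsmt() and dsmt() wrap the heuristics and return
# classed objects with print/summary/plot methods.

#' Fit a rectilinear Steiner minimum tree to FISH patterns
#'
#' The main entry point. Reconstructs an approximate RSMT over the distinct
#' cell count patterns by one of three routes: `"mpt"` (parsimony search
#' plus internal-node labeling — the strongest heuristic), `"mst"`
#' (minimum spanning tree plus iterative median insertion) or `"exact"`
#' (the small-instance optimal solver).
#'
#' @param x a `fish_patterns` object, pattern matrix or data frame.
#' @param method `"mpt"` (default), `"mst"` or `"exact"`.
#' @param config a [search_config()] controlling the parsimony search.
#' @param max_terminals,max_vertices limits for the exact solver.
#' @return an object of class `rsmt`: list with `tree` (a `steiner_tree`),
#'   `weight`, `steiner_nodes`, `method`, `provenance` (for `"mpt"`),
#'   `seed`, `seconds` and the `call`.
#' @examples
#' x <- rbind(c(0, 0), c(4, 2), c(2, 6))
#' fit <- rsmt(x, method = "mst")
#' fit$weight  # 10
#' @export
rsmt <- function(x, method = c("mpt", "mst", "exact"),
                 config = search_config(), max_terminals = 8L,
                 max_vertices = 5000L) {
  method <- match.arg(method)
  x <- as_fish_patterns(x)
  t0 <- proc.time()[["elapsed"]]
  provenance <- NA_character_
  if (method == "mpt") {
    cand <- derive_rsmt(mpt_search(x, config), x)
    tree <- cand$tree
    provenance <- cand$provenance
  } else if (method == "mst") {
    tree <- msttree(x)
  } else {
    tree <- exact_rsmt(x, max_terminals, max_vertices)$tree
  }
  structure(list(tree = tree, weight = tree_weight(tree),
                 steiner_nodes = count_steiner_nodes(tree, x),
                 method = method, provenance = provenance,
                 n_patterns = nrow(x$counts), n_probes = ncol(x$counts),
                 config = config, seed = config$seed,
                 seconds = proc.time()[["elapsed"]] - t0,
                 call = match.call()),
            class = "rsmt")
}

#' Fit a duplication Steiner minimum tree
#'
#' Like [rsmt()] but under the generalized metric that admits unit-cost
#' chromosomal and whole-genome duplication events (see [dsmttree()]).
#'
#' @param x a `fish_patterns` (carrying a probe-to-chromosome map when
#'   chromosomal duplications are enabled).
#' @param model an [event_model()].
#' @param chromosomes probe-to-chromosome map (defaults to the one in `x`).
#' @param method `"mst"` (default) or `"mpt"` for the subtree rebuilds.
#' @param config a [search_config()].
#' @return an object of class `c("dsmt", "rsmt")` with the additional
#'   element `generalized_weight`.
#' @export
dsmt <- function(x, model = event_model(), chromosomes = NULL,
                 method = c("mst", "mpt"), config = search_config()) {
  method <- match.arg(method)
  x <- as_fish_patterns(x)
  t0 <- proc.time()[["elapsed"]]
  tree <- dsmttree(x, model, chromosomes, method, config)
  structure(list(tree = tree, weight = tree_weight(tree),
                 generalized_weight = attr(tree, "generalized_weight"),
                 dup_branches = attr(tree, "dup_branches"),
                 steiner_nodes = count_steiner_nodes(tree, x),
                 method = method, provenance = NA_character_,
                 n_patterns = nrow(x$counts), n_probes = ncol(x$counts),
                 config = config, seed = config$seed,
                 seconds = proc.time()[["elapsed"]] - t0,
                 call = match.call()),
            class = c("dsmt", "rsmt"))
}

#' @export
print.rsmt <- function(x, ...) {
  cat(sprintf("RSMT fit (%s): %d patterns x %d probes\n", x$method,
              x$n_patterns, x$n_probes))
  cat(sprintf("  tree weight: %d   Steiner nodes: %d\n",
              as.integer(x$weight), x$steiner_nodes))
  if (inherits(x, "dsmt"))
    cat(sprintf("  generalized (duplication) weight: %d   duplication branches: %d\n",
                as.integer(x$generalized_weight),
                if (is.null(x$dup_branches)) 0L else nrow(x$dup_branches)))
  invisible(x)
}

#' @export
summary.rsmt <- function(object, ...) {
  t <- object$tree
  len <- edge_lengths_l1(t)
  deg <- tabulate(t$edges, nbins = nrow(t$labels))
  out <- list(method = object$method, weight = object$weight,
              steiner_nodes = object$steiner_nodes,
              n_nodes = nrow(t$labels), n_edges = nrow(t$edges),
              branch_lengths = if (length(len)) summary(len) else NULL,
              max_degree = if (length(deg)) max(deg) else 0L,
              seconds = object$seconds)
  class(out) <- "summary.rsmt"
  out
}

#' @export
print.summary.rsmt <- function(x, ...) {
  cat(sprintf("%s tree: weight %d, %d nodes (%d Steiner), %d edges\n",
              x$method, as.integer(x$weight), x$n_nodes, x$steiner_nodes,
              x$n_edges))
  if (!is.null(x$branch_lengths)) {
    cat("branch lengths:\n")
    print(x$branch_lengths)
  }
  cat(sprintf("max degree %d; fitted in %.2fs\n", x$max_degree, x$seconds))
  invisible(x)
}

#' @export
plot.rsmt <- function(x, ...) plot(x$tree, ...)
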