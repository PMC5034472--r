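# The labeled progression-tree container and the shared tree operations:
# weight, trivial-edge contraction and Steiner-node accounting.

#' Labeled progression trees
#'
#' A `steiner_tree` is a connected acyclic graph whose nodes are labeled by
#' cell count patterns. Observed nodes carry input patterns; the remaining
#' nodes are inferred (Steiner) states. Edge lengths are implied by the
#' active metric and are recomputed on demand rather than stored.
#'
#' @param labels integer matrix, one row per node, one column per probe.
#' @param edges two-column integer matrix of undirected edges (node indices).
#' @param observed logical vector, one entry per node.
#' @param multiplicity integer vector of cell multiplicities (NA for
#'   unobserved nodes).
#' @param probes probe names (defaults to the column names of `labels`).
#' @param root optional root node index (NA for unrooted trees).
#' @param validate check connectivity/acyclicity (default TRUE).
#' @return an object of class `steiner_tree`.
#' @export
steiner_tree <- function(labels, edges, observed, multiplicity = NULL,
                         probes = NULL, root = NA_integer_, validate = TRUE) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  n <- nrow(labels)
  if (is.null(probes)) probes <- colnames(labels)
  if (is.null(probes)) probes <- paste0("P", seq_len(ncol(labels)))
  colnames(labels) <- probes
  edges <- matrix(as.integer(edges), ncol = 2)
  observed <- as.logical(observed)
  if (length(observed) != n) stop("one observed flag per node required")
  if (is.null(multiplicity)) {
    multiplicity <- ifelse(observed, 1L, NA_integer_)
  }
  multiplicity <- as.integer(multiplicity)
  if (validate) {
    if (any(is.na(labels)) || any(labels < 0))
      stop("node labels must be non-negative integer patterns")
    if (nrow(edges) != n - 1L)
      stop("a tree on ", n, " nodes needs ", n - 1L, " edges")
    if (n > 1L) {
      comp <- tree_components(n, edges)
      if (length(unique(comp)) != 1L) stop("tree is not connected")
    }
  }
  structure(list(labels = labels, edges = edges, observed = observed,
                 multiplicity = multiplicity, probes = probes,
                 root = as.integer(root)),
            class = "steiner_tree")
}

# connected component id per node under the given edge set
tree_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

edge_lengths_l1 <- function(t) {
  if (nrow(t$edges) == 0L) return(integer(0))
  as.integer(rowSums(abs(t$labels[t$edges[, 1], , drop = FALSE] -
                           t$labels[t$edges[, 2], , drop = FALSE])))
}

#' Total tree weight
#'
#' Sum of branch lengths over all edges. Under the `"l1"` metric a branch
#' length is the rectilinear distance between the endpoint patterns; under
#' `"duplication"` it is the generalized event distance of
#' [duplication_distance()] (cheaper orientation for unrooted trees, the
#' rooted orientation when the tree has a root).
#'
#' @param t a `steiner_tree` with all nodes labeled.
#' @param metric `"l1"` (default) or `"duplication"`.
#' @param model an [event_model()], for the duplication metric.
#' @param chromosomes probe-to-chromosome map, for chromosomal duplications.
#' @return a non-negative number.
#' @export
tree_weight <- function(t, metric = c("l1", "duplication"), model = NULL,
                        chromosomes = NULL) {
  metric <- match.arg(metric)
  if (any(is.na(t$labels))) stop("tree has unlabeled nodes")
  if (metric == "l1") return(as.integer(sum(edge_lengths_l1(t))))
  if (is.null(model)) model <- event_model()
  ed <- t$edges
  if (!is.na(t$root) && nrow(ed)) ed <- orient_edges(t, t$root)
  w <- 0
  for (e in seq_len(nrow(ed))) {
    a <- t$labels[ed[e, 1], ]; b <- t$labels[ed[e, 2], ]
    cab <- duplication_distance(a, b, model, chromosomes)$cost
    if (is.na(t$root)) {
      cba <- duplication_distance(b, a, model, chromosomes)$cost
      cab <- min(cab, cba)
    }
    w <- w + cab
  }
  as.integer(w)
}

# orient edges (parent, child) away from root by BFS
orient_edges <- function(t, root) {
  n <- nrow(t$labels)
  adj <- adjacency_list(n, t$edges)
  parent <- rep(NA_integer_, n)
  seen <- logical(n)
  queue <- root
  seen[root] <- TRUE
  out <- matrix(integer(0), ncol = 2)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        out <- rbind(out, c(v, w))
        queue <- c(queue, w)
      }
    }
  }
  out
}

#' Contract all trivial (zero-length) branches
#'
#' Merges every pair of adjacent, identically labeled nodes. When an observed
#' node is merged with an unobserved one the survivor stays observed; the
#' smallest node id among merged observed nodes (else the smallest id) is
#' kept, so the result is deterministic. Tree weight is unchanged and the
#' node count never increases.
#'
#' @param t a fully labeled `steiner_tree`.
#' @return a `steiner_tree` without zero-length edges.
#' @export
contract_trivial_edges <- function(t) {
  if (any(is.na(t$labels))) stop("tree has unlabeled nodes")
  n <- nrow(t$labels)
  len <- edge_lengths_l1(t)
  if (!any(len == 0)) return(t)
  zero <- t$edges[len == 0, , drop = FALSE]
  comp <- tree_components(n, zero)
  # representative per component: smallest observed id, else smallest id
  keep <- integer(0)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    obs <- members[t$observed[members]]
    keep[as.character(cc)] <- if (length(obs)) min(obs) else min(members)
  }
  rep_of <- keep[as.character(comp)]
  new_ids <- sort(unique(rep_of))
  remap <- match(rep_of, new_ids)
  labels <- t$labels[new_ids, , drop = FALSE]
  observed <- vapply(new_ids, function(i) any(t$observed[comp == comp[i]]),
                     logical(1))
  multiplicity <- vapply(new_ids, function(i) {
    mm <- t$multiplicity[comp == comp[i]]
    if (all(is.na(mm))) NA_integer_ else as.integer(max(mm, na.rm = TRUE))
  }, integer(1))
  ed <- cbind(remap[t$edges[, 1]], remap[t$edges[, 2]])
  ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
  root <- if (is.na(t$root)) NA_integer_ else remap[t$root]
  steiner_tree(labels, ed, observed, multiplicity, t$probes, root)
}

#' Count Steiner nodes of a tree
#'
#' A node is a Steiner node iff its label is not among the input patterns,
#' regardless of how the tree was constructed.
#'
#' @param t a fully labeled `steiner_tree`.
#' @param inputs the observed `fish_patterns` (or a pattern matrix).
#' @return a non-negative integer.
#' @export
count_steiner_nodes <- function(t, inputs) {
  if (any(is.na(t$labels))) stop("tree has unlabeled nodes")
  inputs <- as_fish_patterns(inputs)
  sum(!(pattern_key(t$labels) %in% pattern_key(inputs$counts)))
}

#' @export
print.steiner_tree <- function(x, ...) {
  cat(sprintf("steiner_tree: %d nodes (%d observed), %d edges, L1 weight %d\n",
              nrow(x$labels), sum(x$observed), nrow(x$edges),
              tree_weight(x)))
  invisible(x)
}

#' Plot a progression tree
#'
#' Draws the tree with observed patterns as white nodes and inferred Steiner
#' states as red nodes (requires the igraph package).
#'
#' @param x a `steiner_tree`.
#' @param ... passed on to `igraph::plot.igraph`.
#' @export
plot.steiner_tree <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the igraph package")
  g <- igraph::graph_from_edgelist(x$edges, directed = FALSE)
  igraph::V(g)$label <- pattern_label(x$labels)
  igraph::V(g)$color <- ifelse(x$observed, "white", "tomato")
  lay <- if (!is.na(x$root)) igraph::layout_as_tree(g, root = x$root)
         else igraph::layout_with_fr(g)
  igraph::plot.igraph(g, layout = lay, vertex.label.cex = 0.7,
                      edge.label = edge_lengths_l1(x), ...)
  invisible(x)
}
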