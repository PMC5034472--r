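# Duplication Steiner minimum tree (DSMT): a generalized edge metric that
# admits unit-cost chromosomal and whole-genome duplication events, plus the
# branch-removal / per-subtree-rebuild / reassembly pipeline that extends the
# RSMT heuristics to trees with large-scale duplications.

#' Mutation event model
#'
#' Admissible events along a branch, each at unit cost: single-gene gain
#' (+1 on one probe), single-gene loss (-1 on one probe), chromosomal
#' duplication (double all probes on one chromosome) and whole-genome
#' duplication (double all probes). Doublings apply to the pre-event counts;
#' at most one WGD and at most one duplication per chromosome are allowed on
#' a single branch.
#'
#' @param gain,loss,chromosomal,wgd enable the event kinds.
#' @return an object of class `event_model`.
#' @export
event_model <- function(gain = TRUE, loss = TRUE, chromosomal = TRUE,
                        wgd = TRUE) {
  structure(list(gain = gain, loss = loss, chromosomal = chromosomal,
                 wgd = wgd),
            class = "event_model")
}

# all admissible duplication sets: WGD yes/no x subset of chromosomes; each
# returns the per-probe doubling exponent and the event script
dup_sets <- function(model, chromosomes, probes) {
  sets <- list(list(factor = rep(1L, length(probes)), script = character(0)))
  chroms <- character(0)
  if (isTRUE(model$chromosomal)) {
    if (is.null(chromosomes))
      stop("chromosomal duplications require a probe-to-chromosome map")
    chroms <- unique(unname(chromosomes[probes]))
  }
  wgd_opts <- if (isTRUE(model$wgd)) c(FALSE, TRUE) else FALSE
  out <- list()
  for (w in wgd_opts) {
    nch <- length(chroms)
    subsets <- if (nch) 0:(2^nch - 1) else 0
    for (s in subsets) {
      inset <- if (nch) as.logical(bitwAnd(s, 2^(0:(nch - 1)))) else logical(0)
      fac <- rep(1L, length(probes))
      script <- character(0)
      if (w) {
        fac <- fac * 2L
        script <- "wgd"
      }
      if (any(inset)) {
        on <- chromosomes[probes] %in% chroms[inset]
        fac[on] <- fac[on] * 2L
        script <- c(script, paste0("dup:", chroms[inset]))
      }
      out[[length(out) + 1L]] <- list(factor = fac, script = script)
    }
  }
  out
}

#' Generalized (duplication-aware) branch distance
#'
#' Minimum event count turning `parent` into `child`: apply a set of
#' duplications (at most one whole-genome doubling plus at most one doubling
#' per chromosome) to the parent, then bridge the remainder with unit
#' single-gene gains/losses. The minimum over all duplication sets (including
#' the empty one, i.e. the plain L1 distance) is found exhaustively; with
#' small probe panels the grammar has at most `2^(c+1)` sets for `c`
#' chromosomes. The distance is directional; for an unrooted edge take the
#' cheaper orientation.
#'
#' @param parent,child integer count patterns of equal length.
#' @param model an [event_model()].
#' @param chromosomes named character vector probe -> chromosome (needed when
#'   chromosomal duplications are enabled).
#' @return list with `cost`, the duplication `script` (character vector,
#'   empty when no duplication helps) and `residual` (the single-gene event
#'   count after the duplications).
#' @examples
#' m <- event_model(chromosomal = FALSE)
#' duplication_distance(c(2, 2, 2, 2), c(4, 4, 4, 4), m)$cost  # 1 (one WGD)
#' @export
duplication_distance <- function(parent, child, model = event_model(),
                                 chromosomes = NULL) {
  parent <- as.integer(parent); child <- as.integer(child)
  if (length(parent) != length(child))
    stop("patterns have different numbers of probes")
  probes <- names(parent)
  if (is.null(probes)) {
    probes <- if (!is.null(names(chromosomes)) &&
                  length(chromosomes) >= length(parent))
      names(chromosomes)[seq_along(parent)] else paste0("P", seq_along(parent))
  }
  best <- NULL
  for (s in dup_sets(model, chromosomes, probes)) {
    resid <- sum(abs(parent * s$factor - child))
    cost <- length(s$script) + resid
    if (is.null(best) || cost < best$cost) {
      best <- list(cost = cost, script = s$script, residual = resid)
    }
  }
  best
}

# symmetric generalized distance matrix over the rows of P (vectorized over
# duplication sets); used to seed the DSMT pipeline
dup_dist_matrix <- function(P, model, chromosomes) {
  n <- nrow(P)
  probes <- colnames(P)
  D <- as.matrix(stats::dist(P, method = "manhattan"))
  for (s in dup_sets(model, chromosomes, probes)) {
    if (!length(s$script)) next
    Tm <- sweep(P, 2, s$factor, `*`)
    M <- matrix(0, n, n)
    for (j in seq_len(ncol(P)))
      M <- M + abs(outer(Tm[, j], P[, j], `-`))
    M <- M + length(s$script)
    D <- pmin(D, M, t(M))  # either orientation of the directional metric
  }
  D
}

#' Locate branches carrying large-scale duplications
#'
#' Roots the tree at the diploid pattern when present (else at the pattern
#' with the smallest total count) and flags every parent-to-child edge whose
#' generalized distance is strictly below its L1 length, together with the
#' duplication script.
#'
#' @param t a fully labeled `steiner_tree`.
#' @param model an [event_model()].
#' @param chromosomes probe-to-chromosome map.
#' @return data frame with columns `parent`, `child`, `l1`, `cost`,
#'   `residual` and `script` (";"-joined), one row per flagged edge.
#' @export
detect_duplication_branches <- function(t, model = event_model(),
                                        chromosomes = NULL) {
  if (any(is.na(t$labels))) stop("tree has unlabeled nodes")
  root <- dsmt_root(t)
  ed <- if (nrow(t$edges)) orient_edges(t, root) else t$edges
  out <- data.frame(parent = integer(0), child = integer(0), l1 = integer(0),
                    cost = integer(0), residual = integer(0),
                    script = character(0), stringsAsFactors = FALSE)
  for (e in seq_len(nrow(ed))) {
    a <- t$labels[ed[e, 1], ]; b <- t$labels[ed[e, 2], ]
    l1 <- l1_dist(a, b)
    dd <- duplication_distance(a, b, model, chromosomes)
    if (dd$cost < l1) {
      out <- rbind(out, data.frame(
        parent = ed[e, 1], child = ed[e, 2], l1 = l1, cost = dd$cost,
        residual = dd$residual, script = paste(dd$script, collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  out
}

dsmt_root <- function(t) {
  key <- pattern_key(t$labels)
  dip <- which(key == pattern_key(matrix(diploid_pattern(ncol(t$labels)),
                                         nrow = 1)))
  if (length(dip)) return(dip[1])
  tot <- rowSums(t$labels)
  cand <- which(tot == min(tot))
  cand[order(key[cand])][1]
}

#' Split at duplication branches, rebuild each subtree, reassemble
#'
#' Removes the flagged duplication branches, re-solves each resulting
#' component as a plain RSMT over the patterns it contains (MST-based or
#' MPT-based heuristic) and re-inserts the removed branches between the
#' nodes carrying the original endpoint patterns. Endpoints that are
#' unobserved in the input tree are carried into the rebuild as required
#' patterns so reassembly always succeeds.
#'
#' @param t a fully labeled `steiner_tree` (the seed tree).
#' @param x the observed `fish_patterns`.
#' @param method `"mst"` or `"mpt"` RSMT heuristic for the rebuilds.
#' @param model an [event_model()].
#' @param chromosomes probe-to-chromosome map.
#' @param config a [search_config()] for the MPT rebuilds.
#' @return a `steiner_tree`; attribute `"dup_branches"` records the
#'   re-inserted branches and their event scripts.
#' @export
split_rebuild_reassemble <- function(t, x, method = c("mst", "mpt"),
                                     model = event_model(),
                                     chromosomes = NULL,
                                     config = search_config()) {
  method <- match.arg(method)
  x <- as_fish_patterns(x)
  br <- detect_duplication_branches(t, model, chromosomes)
  n <- nrow(t$labels)
  drop <- rep(FALSE, nrow(t$edges))
  if (nrow(br)) {
    for (i in seq_len(nrow(br))) {
      drop <- drop | (t$edges[, 1] == br$parent[i] &
                        t$edges[, 2] == br$child[i]) |
        (t$edges[, 1] == br$child[i] & t$edges[, 2] == br$parent[i])
    }
  }
  comp <- tree_components(n, t$edges[!drop, , drop = FALSE])
  key_in <- pattern_key(x$counts)
  pieces <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    endpoints <- members[members %in% c(br$parent, br$child)]
    req <- unique(c(members[t$observed[members]], endpoints))
    P <- t$labels[req, , drop = FALSE]
    keyP <- pattern_key(P)
    P <- P[!duplicated(keyP), , drop = FALSE]
    mult <- x$multiplicity[match(pattern_key(P), key_in)]
    mult[is.na(mult)] <- 1L
    sub <- fish_patterns(P, mult, x$chromosomes)
    rebuilt <- if (method == "mst") msttree(sub)
               else derive_rsmt(mpt_search(sub, config), sub)$tree
    pieces[[as.character(cc)]] <- rebuilt
  }
  # assemble: concatenate the pieces, then re-insert the removed branches
  offset <- c()
  labels <- NULL; observed <- logical(0); mult <- integer(0)
  ed <- matrix(integer(0), ncol = 2)
  for (cc in names(pieces)) {
    p <- pieces[[cc]]
    offset[cc] <- if (is.null(labels)) 0L else nrow(labels)
    if (nrow(p$edges)) ed <- rbind(ed, p$edges + offset[cc])
    labels <- rbind(labels, p$labels)
    observed <- c(observed, p$observed)
    mult <- c(mult, p$multiplicity)
  }
  locate <- function(node) {
    cc <- as.character(comp[node])
    key <- pattern_key(t$labels[node, , drop = FALSE])
    hit <- which(pattern_key(pieces[[cc]]$labels) == key)
    offset[cc] + hit[1]
  }
  if (nrow(br)) {
    for (i in seq_len(nrow(br)))
      ed <- rbind(ed, c(locate(br$parent[i]), locate(br$child[i])))
  }
  observed <- pattern_key(labels) %in% key_in
  out <- steiner_tree(labels, ed, observed, mult, t$probes)
  out$root <- dsmt_root(out)
  attr(out, "dup_branches") <- br
  out
}

#' DSMT heuristic (generalized-metric seed, split, rebuild, reassemble)
#'
#' Builds a seed tree as the minimum spanning tree under the generalized
#' duplication metric (rooted at the diploid pattern when observed), applies
#' [split_rebuild_reassemble()], and keeps the cheaper of the result and the
#' plain RSMT heuristic tree evaluated under the generalized metric —
#' duplication events can only reduce the cost.
#'
#' @param x the observed `fish_patterns` (carrying the chromosome map if
#'   chromosomal duplications are enabled).
#' @param model an [event_model()].
#' @param chromosomes probe-to-chromosome map (defaults to the one in `x`).
#' @param method `"mst"` or `"mpt"` for the RSMT rebuilds.
#' @param config a [search_config()].
#' @return a `steiner_tree` with attributes `"generalized_weight"` and
#'   `"dup_branches"`.
#' @export
dsmttree <- function(x, model = event_model(), chromosomes = NULL,
                     method = c("mst", "mpt"), config = search_config()) {
  method <- match.arg(method)
  x <- as_fish_patterns(x)
  if (is.null(chromosomes)) chromosomes <- x$chromosomes
  if (isTRUE(model$chromosomal) && is.null(chromosomes))
    stop("chromosomal duplications require a probe-to-chromosome map")
  P <- x$counts
  n <- nrow(P)
  if (n == 1L) {
    out <- steiner_tree(P, matrix(integer(0), ncol = 2), TRUE,
                        x$multiplicity)
    attr(out, "generalized_weight") <- 0L
    return(out)
  }
  D <- dup_dist_matrix(P, model, chromosomes)
  seed <- kruskal_from_matrix(P, D, x$multiplicity)
  seed$root <- dsmt_root(seed)
  built <- split_rebuild_reassemble(seed, x, method, model, chromosomes,
                                    config)
  plain <- if (method == "mst") msttree(x)
           else derive_rsmt(mpt_search(x, config), x)$tree
  plain$root <- dsmt_root(plain)
  wb <- tree_weight(built, "duplication", model, chromosomes)
  wp <- tree_weight(plain, "duplication", model, chromosomes)
  out <- if (wb <= wp) built else plain
  attr(out, "generalized_weight") <- min(wb, wp)
  if (is.null(attr(out, "dup_branches")))
    attr(out, "dup_branches") <- detect_duplication_branches(out, model,
                                                             chromosomes)
  out
}

# Kruskal MST from a precomputed symmetric distance matrix, with the same
# deterministic tie-breaking as build_mst()
kruskal_from_matrix <- function(P, D, multiplicity) {
  n <- nrow(P)
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
  steiner_tree(P, ed, rep(TRUE, n), multiplicity, colnames(P))
}
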