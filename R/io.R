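# Readers and writers: FISH count TSV, probe-to-chromosome map, Newick plus
# nodes/edges TSV plus a JSON run summary.

#' Read a FISH count table
#'
#' Expects a TSV with a header row of probe names and one row of
#' non-negative integer counts per cell pattern; an optional column named
#' `count` gives the number of cells per row. Duplicate patterns are merged
#' with summed multiplicities (with a warning).
#'
#' @param path path to the counts TSV.
#' @param panel_path optional probe-to-chromosome TSV with columns `probe`
#'   and `chromosome`.
#' @return a `fish_patterns` object.
#' @export
read_fish_tsv <- function(path, panel_path = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty FISH file: ", path)
  cols <- names(raw)
  count_col <- which(tolower(cols) == "count")
  mult <- NULL
  if (length(count_col)) {
    mult <- raw[[count_col[1]]]
    raw <- raw[, -count_col[1], drop = FALSE]
  }
  for (j in seq_along(raw)) {
    bad <- which(!grepl("^\\s*[0-9]+\\s*$", raw[[j]]))
    if (length(bad))
      stop(sprintf("invalid count at row %d column %d (probe %s): '%s'",
                   bad[1], j, names(raw)[j], raw[[j]][bad[1]]))
  }
  counts <- vapply(raw, function(col) as.integer(col),
                   integer(nrow(raw)))
  counts <- matrix(counts, nrow = nrow(raw),
                   dimnames = list(NULL, names(raw)))
  if (!is.null(mult)) {
    bad <- which(!grepl("^\\s*[0-9]+\\s*$", mult) | as.integer(mult) < 1)
    if (length(bad))
      stop(sprintf("invalid multiplicity at row %d: '%s'", bad[1],
                   mult[bad[1]]))
    mult <- as.integer(mult)
  }
  chromosomes <- if (!is.null(panel_path)) read_chromosome_map(panel_path)
                 else NULL
  if (anyDuplicated(pattern_key(counts)))
    warning("duplicate patterns merged (multiplicities summed)")
  fish_patterns(counts, mult, chromosomes)
}

#' Read a probe-to-chromosome map
#'
#' @param path TSV with columns `probe` and `chromosome`.
#' @return named character vector, probe -> chromosome.
#' @export
read_chromosome_map <- function(path) {
  map <- utils::read.delim(path, colClasses = "character")
  need <- c("probe", "chromosome")
  if (!all(need %in% names(map)))
    stop("chromosome map needs columns 'probe' and 'chromosome'")
  stats::setNames(map$chromosome, map$probe)
}

newick_string <- function(t) {
  n <- nrow(t$labels)
  lab <- pattern_label(t$labels)
  if (n == 1L) return(paste0("(", lab[1], ");"))
  root <- if (!is.na(t$root)) t$root else 1L
  adj <- adjacency_list(n, t$edges)
  len <- function(a, b) l1_dist(t$labels[a, ], t$labels[b, ])
  rec <- function(v, from) {
    kids <- setdiff(adj[[v]], from)
    body <- if (length(kids)) {
      paste0("(", paste(vapply(kids, function(k) {
        paste0(rec(k, v), ":", len(v, k))
      }, character(1)), collapse = ","), ")")
    } else ""
    paste0(body, lab[v])
  }
  paste0(rec(root, NA_integer_), ";")
}

#' Write a progression tree to disk
#'
#' Writes four files under a common prefix: `<prefix>.nwk` (Newick; node
#' labels are the count patterns joined by `"."`, branch lengths are L1
#' edge lengths), `<prefix>.nodes.tsv` (id, pattern, observed/steiner flag,
#' multiplicity), `<prefix>.edges.tsv` (parent, child, length, event script)
#' and `<prefix>.summary.json` (the run summary). Reading the nodes/edges
#' pair back with [read_tree()] reproduces the weight and Steiner count
#' exactly.
#'
#' @param tree a fully labeled `steiner_tree`, or an `rsmt`/`dsmt` fit.
#' @param prefix output path prefix.
#' @param method,seed,parameters,seconds optional run metadata for the
#'   summary (taken from the fit object when one is given).
#' @return invisibly, the vector of written file paths.
#' @export
write_tree <- function(tree, prefix, method = NA_character_, seed = NA,
                       parameters = list(), seconds = NA_real_) {
  if (inherits(tree, "rsmt")) {
    fit <- tree
    tree <- fit$tree
    if (is.na(method)) method <- fit$method
    if (is.na(seed)) seed <- fit$seed
    if (is.na(seconds)) seconds <- fit$seconds
  }
  if (any(is.na(tree$labels))) stop("tree has unlabeled nodes")
  n <- nrow(tree$labels)
  root <- if (!is.na(tree$root)) tree$root else 1L
  nwk <- paste0(prefix, ".nwk")
  writeLines(newick_string(tree), nwk)
  nodes <- data.frame(
    id = seq_len(n),
    pattern = pattern_label(tree$labels),
    type = ifelse(tree$observed, "observed", "steiner"),
    multiplicity = tree$multiplicity,
    stringsAsFactors = FALSE)
  nodes_path <- paste0(prefix, ".nodes.tsv")
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ed <- if (nrow(tree$edges)) orient_edges(tree, root) else tree$edges
  scripts <- rep("", nrow(ed))
  br <- attr(tree, "dup_branches")
  if (!is.null(br) && nrow(br)) {
    for (i in seq_len(nrow(br))) {
      hit <- (ed[, 1] == br$parent[i] & ed[, 2] == br$child[i]) |
        (ed[, 1] == br$child[i] & ed[, 2] == br$parent[i])
      scripts[hit] <- br$script[i]
    }
  }
  edges <- data.frame(
    parent = ed[, 1], child = ed[, 2],
    length = if (nrow(ed)) rowSums(abs(tree$labels[ed[, 1], , drop = FALSE] -
                                         tree$labels[ed[, 2], , drop = FALSE]))
             else integer(0),
    events = scripts, stringsAsFactors = FALSE)
  edges_path <- paste0(prefix, ".edges.tsv")
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_path <- paste0(prefix, ".summary.json")
  summ <- list(method = method, weight = tree_weight(tree),
               steiner_nodes = sum(!tree$observed),
               n_nodes = n, n_edges = nrow(tree$edges),
               parameters = parameters, seed = seed,
               wall_time_s = seconds, probes = tree$probes)
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(nwk, nodes_path, edges_path, summary_path))
}

#' Read a progression tree written by [write_tree()]
#'
#' Rebuilds the `steiner_tree` from the nodes and edges TSV pair.
#'
#' @param prefix the path prefix used when writing.
#' @return a `steiner_tree`.
#' @export
read_tree <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, ".nodes.tsv"),
                             colClasses = "character")
  edges <- utils::read.delim(paste0(prefix, ".edges.tsv"),
                             colClasses = "character")
  labels <- do.call(rbind, lapply(strsplit(nodes$pattern, ".", fixed = TRUE),
                                  as.integer))
  ed <- cbind(as.integer(edges$parent), as.integer(edges$child))
  if (nrow(edges) == 0L) ed <- matrix(integer(0), ncol = 2)
  mult <- suppressWarnings(as.integer(nodes$multiplicity))
  root <- if (nrow(ed)) setdiff(ed[, 1], ed[, 2])[1] else 1L
  steiner_tree(labels, ed, nodes$type == "observed", mult,
               root = as.integer(root))
}
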