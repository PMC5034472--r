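# Synthetic tumor progression generator: a budding growth process from a
# diploid ancestor, one mutation event per new lineage, run until the number
# of distinct cell count patterns falls in a target range. Emits both the
# ground-truth lineage tree and the observed pattern set.

#' Simulation configuration
#'
#' The generator grows a rooted lineage tree from the diploid pattern
#' (2,...,2): in each round every existing cell buds a daughter with
#' probability `growth` (the tree growth factor), and every new daughter
#' acquires exactly one mutation event drawn from `events`. Growth stops as
#' soon as the number of distinct patterns lies in `patterns`; a final round
#' that overshoots the upper bound is resampled.
#'
#' @param probes number of gene probes (typical panels: 4, 6 or 8).
#' @param growth per-round budding probability in (0, 1].
#' @param patterns target range `c(lo, hi)` of distinct patterns
#'   (default 120-150).
#' @param events named probability vector over
#'   `c("gain", "loss", "chromosomal", "wgd")`; defaults to gain/loss only
#'   (0.5/0.5). Must sum to 1.
#' @param chromosomes optional named probe-to-chromosome map; when
#'   chromosomal duplications have positive probability and no map is given,
#'   probes are assigned round-robin, two per chromosome.
#' @param zero_absorbing when TRUE (default) a probe lost to copy number 0
#'   can never be regained.
#' @param seed integer seed; mandatory, so every sample is reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(probes = 4L, growth = 0.4, patterns = c(120L, 150L),
                       events = NULL, chromosomes = NULL,
                       zero_absorbing = TRUE, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  probes <- as.integer(probes)
  if (probes < 1L) stop("need at least one probe")
  if (growth <= 0 || growth > 1) stop("growth must lie in (0, 1]")
  patterns <- as.integer(patterns)
  if (length(patterns) != 2L || patterns[1] > patterns[2] || patterns[2] < 1L)
    stop("patterns must be a valid range c(lo, hi) with hi >= max(lo, 1)")
  if (is.null(events)) events <- c(gain = 0.5, loss = 0.5)
  full <- c(gain = 0, loss = 0, chromosomal = 0, wgd = 0)
  full[names(events)] <- events
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    stop("event probabilities must be non-negative and sum to 1")
  probe_names <- paste0("P", seq_len(probes))
  if (is.null(chromosomes) && full["chromosomal"] > 0) {
    chromosomes <- stats::setNames(
      paste0("chr", ceiling(seq_len(probes) / 2)), probe_names)
  }
  structure(list(probes = probes, growth = growth, patterns = patterns,
                 events = full, chromosomes = chromosomes,
                 zero_absorbing = isTRUE(zero_absorbing),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one mutation event applied to a pattern; returns the new pattern and the
# event actually applied ("none" when no eligible probe exists)
apply_event <- function(pat, kind, cfg) {
  d <- length(pat)
  if (kind == "gain") {
    ok <- if (cfg$zero_absorbing) which(pat > 0L) else seq_len(d)
    if (!length(ok)) return(list(pat = pat, event = "none"))
    j <- if (length(ok) == 1L) ok else sample(ok, 1L)
    pat[j] <- pat[j] + 1L
    return(list(pat = pat, event = paste0("gain:", j)))
  }
  if (kind == "loss") {
    ok <- which(pat > 0L)
    if (!length(ok)) return(list(pat = pat, event = "none"))
    j <- if (length(ok) == 1L) ok else sample(ok, 1L)
    pat[j] <- pat[j] - 1L
    return(list(pat = pat, event = paste0("loss:", j)))
  }
  if (kind == "chromosomal") {
    chroms <- unique(unname(cfg$chromosomes))
    ch <- if (length(chroms) == 1L) chroms else sample(chroms, 1L)
    on <- unname(cfg$chromosomes) == ch
    pat[on] <- pat[on] * 2L
    return(list(pat = pat, event = paste0("dup:", ch)))
  }
  # whole-genome duplication
  list(pat = pat * 2L, event = "wgd")
}

#' Grow a simulated tumor sample
#'
#' Runs the budding process of [sim_config()] and returns the ground-truth
#' lineage tree together with the observed pattern set (distinct patterns
#' with cell multiplicities). Identical configuration and seed give
#' identical output.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `fish_sim`: list with `tree` (the ground-truth
#'   `steiner_tree`, rooted at the diploid founder), `patterns` (a
#'   `fish_patterns`), `events` (per-edge event labels) and `event_count`
#'   (number of effective mutation events).
#' @examples
#' s <- grow_tree(sim_config(probes = 4, growth = 0.5,
#'                           patterns = c(20, 30), seed = 7))
#' s$patterns
#' @export
grow_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  d <- cfg$probes
  lo <- cfg$patterns[1]; hi <- cfg$patterns[2]
  pats <- matrix(diploid_pattern(d), nrow = 1)
  parent <- NA_integer_
  events <- NA_character_
  n_distinct <- 1L
  if (n_distinct >= lo && n_distinct <= hi) {
    return(finish_sim(cfg, pats, parent, events))
  }
  attempts <- 0L
  repeat {
    nn <- nrow(pats)
    if (nn > 1e6) stop("simulation exceeded 1,000,000 cells")
    saved <- get(".Random.seed", .GlobalEnv)
    budders <- which(stats::runif(nn) < cfg$growth)
    if (!length(budders)) next
    kinds <- sample(names(cfg$events), length(budders), replace = TRUE,
                    prob = cfg$events)
    new_pats <- matrix(0L, length(budders), d)
    new_events <- character(length(budders))
    for (i in seq_along(budders)) {
      res <- apply_event(pats[budders[i], ], kinds[i], cfg)
      new_pats[i, ] <- res$pat
      new_events[i] <- res$event
    }
    all_pats <- rbind(pats, new_pats)
    n_distinct <- length(unique(pattern_key(all_pats)))
    if (n_distinct > hi) {
      attempts <- attempts + 1L
      if (attempts <= 50L) {
        # overshot the target: resample this round
        assign(".Random.seed", saved, .GlobalEnv)
        invisible(stats::runif(1))  # perturb the stream before retrying
        next
      }
      # a whole round keeps overshooting (large populations add many new
      # patterns at once): accept daughters one at a time until the distinct
      # count first reaches the range - each adds at most one new pattern
      seen <- unique(pattern_key(pats))
      take <- 0L
      for (i in seq_along(budders)) {
        take <- i
        seen <- union(seen, pattern_key(new_pats[i, , drop = FALSE]))
        if (length(seen) >= lo) break
      }
      keep <- seq_len(take)
      pats <- rbind(pats, new_pats[keep, , drop = FALSE])
      parent <- c(parent, budders[keep])
      events <- c(events, new_events[keep])
      n_distinct <- length(seen)
      break
    }
    pats <- all_pats
    parent <- c(parent, budders)
    events <- c(events, new_events)
    if (n_distinct >= lo) break
  }
  finish_sim(cfg, pats, parent, events)
}

finish_sim <- function(cfg, pats, parent, events) {
  colnames(pats) <- paste0("P", seq_len(ncol(pats)))
  nn <- nrow(pats)
  ed <- if (nn > 1L) cbind(parent[-1], seq_len(nn)[-1])
        else matrix(integer(0), ncol = 2)
  tree <- steiner_tree(pats, ed, rep(TRUE, nn),
                       rep(1L, nn), colnames(pats), root = 1L)
  key <- pattern_key(pats)
  first <- !duplicated(key)
  mult <- as.integer(table(key)[key[first]])
  patterns <- fish_patterns(pats[first, , drop = FALSE], mult,
                            cfg$chromosomes)
  structure(list(tree = tree, patterns = patterns, events = events,
                 event_count = sum(!is.na(events) & events != "none"),
                 config = cfg),
            class = "fish_sim")
}

#' @export
print.fish_sim <- function(x, ...) {
  cat(sprintf(
    "simulated sample: %d cells, %d distinct patterns, %d mutation events\n",
    nrow(x$tree$labels), nrow(x$patterns$counts), x$event_count))
  invisible(x)
}

#' Benchmark tree heuristics on simulated samples
#'
#' Simulates `replicates` samples per configuration, runs each requested
#' method and tabulates tree weights, Steiner node counts and runtimes, plus
#' the fraction of replicates in which each method attains the per-replicate
#' minimum weight (ties count for every attaining method). The exact solver
#' is skipped with a warning on instances beyond its limits.
#'
#' @param methods subset of `c("mst", "msttree", "mpttree", "dsmttree",
#'   "exact")`.
#' @param cfgs list of [sim_config()] objects (a single config is accepted).
#' @param replicates replicates per configuration; replicate `i` uses seed
#'   `cfg$seed + i - 1`.
#' @param config [search_config()] used by `mpttree`/`dsmttree`.
#' @param model [event_model()] used by `dsmttree`.
#' @return an object of class `fish_benchmark`: list with the per-replicate
#'   `results` data frame and the `best` fraction summary.
#' @export
benchmark_methods <- function(methods = c("mst", "msttree", "mpttree"),
                              cfgs, replicates = 10L,
                              config = search_config(),
                              model = event_model()) {
  methods <- match.arg(methods,
                       c("mst", "msttree", "mpttree", "dsmttree", "exact"),
                       several.ok = TRUE)
  if (inherits(cfgs, "sim_config")) cfgs <- list(cfgs)
  rows <- list()
  for (ci in seq_along(cfgs)) {
    base <- cfgs[[ci]]
    for (r in seq_len(replicates)) {
      cfg <- base
      cfg$seed <- base$seed + r - 1L
      sim <- grow_tree(cfg)
      x <- sim$patterns
      for (m in methods) {
        t0 <- proc.time()[["elapsed"]]
        res <- switch(m,
          mst = {
            t <- build_mst(x)
            list(w = tree_weight(t), s = count_steiner_nodes(t, x))
          },
          msttree = {
            t <- msttree(x)
            list(w = tree_weight(t), s = count_steiner_nodes(t, x))
          },
          mpttree = {
            cand <- derive_rsmt(mpt_search(x, config), x)
            list(w = cand$weight, s = cand$steiner_nodes)
          },
          dsmttree = {
            t <- dsmttree(x, model, cfg$chromosomes)
            list(w = attr(t, "generalized_weight"),
                 s = count_steiner_nodes(t, x))
          },
          exact = tryCatch({
            e <- exact_rsmt(x)
            list(w = e$weight, s = count_steiner_nodes(e$tree, x))
          }, error = function(e) {
            warning("exact solver skipped: ", conditionMessage(e),
                    call. = FALSE)
            NULL
          }))
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          config = ci, replicate = r, method = m, weight = res$w,
          steiner = res$s,
          seconds = proc.time()[["elapsed"]] - t0,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  # fraction of replicates where each method attains the minimum weight
  frac <- lapply(split(results, results$config), function(df) {
    per <- split(df, df$replicate)
    hits <- sapply(methods, function(m) {
      mean(vapply(per, function(p) {
        any(p$method == m & p$weight == min(p$weight))
      }, logical(1)))
    })
    data.frame(config = df$config[1], method = methods,
               best_fraction = as.numeric(hits), stringsAsFactors = FALSE)
  })
  structure(list(results = results, best = do.call(rbind, frac)),
            class = "fish_benchmark")
}

#' @export
print.fish_benchmark <- function(x, ...) {
  cat("benchmark on", length(unique(x$results$replicate)), "replicates\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}
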