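# Input container: the distinct cell count patterns of one FISH sample.

#' FISH cell count pattern sets
#'
#' A `fish_patterns` object holds the distinct cell count patterns observed in
#' one FISH sample: an `n x d` matrix of non-negative integer gene copy
#' numbers (one row per distinct pattern, one column per gene probe), the
#' number of cells observed with each pattern, and an optional probe-to-
#' chromosome map needed for chromosomal duplication events.
#'
#' Duplicated rows are merged (multiplicities summed) so the stored patterns
#' are pairwise distinct, as the tree problems are defined over distinct
#' patterns only.
#'
#' @param counts matrix or data frame of non-negative integer copy numbers;
#'   columns are probes.
#' @param multiplicity positive integer vector, cells observed per row
#'   (default 1 each).
#' @param chromosomes optional named character vector mapping every probe name
#'   to a chromosome label.
#' @return an object of class `fish_patterns`.
#' @examples
#' x <- fish_patterns(rbind(c(2, 2), c(4, 2), c(2, 6)))
#' x
#' @export
fish_patterns <- function(counts, multiplicity = NULL, chromosomes = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty pattern set")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("P", seq_len(ncol(counts)))
  rownames(counts) <- NULL
  if (is.null(multiplicity)) multiplicity <- rep(1L, nrow(counts))
  multiplicity <- as.integer(multiplicity)
  if (length(multiplicity) != nrow(counts) || any(is.na(multiplicity)) ||
      any(multiplicity < 1L))
    stop("multiplicity must be a positive integer per pattern")
  key <- pattern_key(counts)
  if (anyDuplicated(key)) {
    multiplicity <- as.integer(tapply(multiplicity, key, sum)[unique(key)])
    counts <- counts[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(chromosomes)) {
    chromosomes <- vapply(chromosomes, as.character, character(1))
    missing <- setdiff(colnames(counts), names(chromosomes))
    if (length(missing))
      stop("chromosome map misses probe(s): ", paste(missing, collapse = ", "))
    chromosomes <- chromosomes[colnames(counts)]
  }
  structure(list(counts = counts, multiplicity = multiplicity,
                 chromosomes = chromosomes),
            class = "fish_patterns")
}

#' Coerce to a FISH pattern set
#'
#' @param x a `fish_patterns` object, matrix or data frame.
#' @return a `fish_patterns` object.
#' @export
as_fish_patterns <- function(x) {
  if (inherits(x, "fish_patterns")) return(x)
  fish_patterns(x)
}

#' @export
print.fish_patterns <- function(x, ...) {
  cat(sprintf("FISH pattern set: %d distinct patterns x %d probes (%d cells)\n",
              nrow(x$counts), ncol(x$counts), sum(x$multiplicity)))
  cat("probes:", paste(colnames(x$counts), collapse = ", "), "\n")
  if (!is.null(x$chromosomes))
    cat("chromosomes:", paste(unique(x$chromosomes), collapse = ", "), "\n")
  invisible(x)
}

n_patterns <- function(x) nrow(x$counts)
n_probes <- function(x) ncol(x$counts)

# Fixed-width key so string order equals lexicographic pattern order.
pattern_key <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  apply(matrix(sprintf("%06d", m), nrow = nrow(m)), 1, paste, collapse = ".")
}

# Human-readable label: counts joined by "."
pattern_label <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  apply(m, 1, paste, collapse = ".")
}

diploid_pattern <- function(d) rep(2L, d)
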