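# The rectilinear (L1) metric and the 3-pattern median.

#' Rectilinear (L1) distance between two count patterns
#'
#' The number of unit single-gene gain/loss events separating two cell count
#' patterns: \eqn{\sum_j |x_j - y_j|}.
#'
#' @param a,b non-negative integer vectors of equal length.
#' @return a non-negative integer.
#' @examples
#' l1_dist(c(2, 1, 4, 2), c(2, 2, 2, 2))  # 3
#' @export
l1_dist <- function(a, b) {
  if (length(a) != length(b))
    stop("patterns have different numbers of probes")
  sum(abs(as.integer(a) - as.integer(b)))
}

#' Per-probe median of three count patterns
#'
#' The pattern minimising the summed L1 distance to three input patterns is
#' the coordinate-wise median, so the optimal Steiner point for three
#' patterns is computable in O(d). The star joining the median to the three
#' inputs has total length \eqn{\sum_j (\max_j - \min_j)}.
#'
#' @param a,b,c non-negative integer vectors of equal length.
#' @return the median pattern (integer vector).
#' @examples
#' median3(c(0, 0), c(4, 2), c(2, 6))  # c(2, 2)
#' @export
median3 <- function(a, b, c) {
  if (length(a) != length(b) || length(b) != length(c))
    stop("patterns have different numbers of probes")
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c)
  a + b + c - pmax(a, b, c) - pmin(a, b, c)
}

#' Does a triple of patterns require a Steiner node?
#'
#' TRUE iff the median of the three patterns differs from all three, i.e. an
#' unobserved intermediate state must be introduced to connect them
#' optimally.
#'
#' @inheritParams median3
#' @return logical.
#' @export
is_steiner_required <- function(a, b, c) {
  m <- median3(a, b, c)
  !identical(m, as.integer(a)) && !identical(m, as.integer(b)) &&
    !identical(m, as.integer(c))
}

#' Exhaustive median of three patterns (validation oracle)
#'
#' Minimises the summed L1 distance over every integer point of the bounding
#' box of the three inputs. Exponential in `d`; intended only to validate
#' [median3()] on small instances.
#'
#' @inheritParams median3
#' @return list with `pattern` (the argmin) and `weight` (the optimal star
#'   weight).
#' @export
exhaustive_median <- function(a, b, c) {
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c)
  if (length(a) != length(b) || length(b) != length(c))
    stop("patterns have different numbers of probes")
  grids <- lapply(seq_along(a), function(j) {
    seq(min(a[j], b[j], c[j]), max(a[j], b[j], c[j]))
  })
  pts <- as.matrix(expand.grid(grids))
  w <- rowSums(abs(sweep(pts, 2, a))) + rowSums(abs(sweep(pts, 2, b))) +
    rowSums(abs(sweep(pts, 2, c)))
  i <- which.min(w)
  list(pattern = as.integer(pts[i, ]), weight = as.integer(w[i]))
}
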