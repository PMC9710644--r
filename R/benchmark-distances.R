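## Benchmark metrics on flat gene-family vectors. These deliberately see
## only the overlap of gene families, which is what the hierarchical
## dissimilarity is designed to improve upon.

.checkAligned <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y)))
    stop("vectors are not aligned: names differ")
}

#' Cosine distance
#'
#' `1 - x.y / (||x|| ||y||)`; in `[0, 1]` for non-negative input. The
#' direction of a zero vector is undefined, so zero vectors are an error
#' (filter degenerate samples upstream).
#'
#' @param x,y aligned non-negative numeric vectors, each with at least one
#'   positive entry.
#' @return a number in `[0, 1]`.
#' @export
cosineDistance <- function(x, y) {
  .checkAligned(x, y)
  if (any(x < 0) || any(y < 0)) stop("negative abundance entry")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine distance is undefined for a zero vector")
  1 - sum(x * y) / (nx * ny)
}

#' Euclidean distance
#'
#' @param x,y aligned numeric vectors.
#' @return `||x - y||`, non-negative.
#' @export
euclideanDistance <- function(x, y) {
  .checkAligned(x, y)
  sqrt(sum((x - y)^2))
}

#' Jensen-Shannon divergence
#'
#' Inputs are renormalized to probability vectors; returns
#' `KL(x||m)/2 + KL(y||m)/2` with `m = (x+y)/2`, natural logarithm and
#' the convention `0 * log(0) = 0`. Bounded by `log(2)`.
#'
#' @param x,y aligned non-negative numeric vectors with positive sums.
#' @return a number in `[0, log(2)]`.
#' @export
jensenShannon <- function(x, y) {
  .checkAligned(x, y)
  if (any(x < 0) || any(y < 0)) stop("negative abundance entry")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 || sy == 0)
    stop("Jensen-Shannon divergence is undefined for a zero-sum vector")
  p <- x / sx; q <- y / sy
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}
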