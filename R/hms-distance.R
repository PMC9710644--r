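## The hierarchical dissimilarity: Bray-Curtis at the gene-family level
## and at each pathway level of the hierarchy, combined as a weighted
## mean. Collapsing and per-pair summation always run in fixed
## (lexicographic index) order in double precision, so results are
## reproducible bit-for-bit regardless of worker count.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)` over aligned non-negative vectors; bounded
#' in `[0, 1]`. Two all-zero vectors are indistinguishable and get
#' distance 0 (avoiding 0/0).
#'
#' @param x,y non-negative numeric vectors of equal length; if both are
#'   named, the names must agree element-wise.
#' @return a number in `[0, 1]`.
#' @examples
#' brayCurtis(c(0.5, 0.5), c(0.25, 0.75))  # 0.25
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length: ", length(x), " vs ", length(y))
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y)))
    stop("vectors are not aligned: names differ")
  if (any(x < 0) || any(y < 0)) stop("negative abundance entry")
  den <- sum(x + y)
  if (den == 0) return(0)
  sum(abs(x - y)) / den
}

## index lists: for each pathway at a level, the positions (in the
## previous level's ordering) that sum into it
.levelIndexLists <- function(h, featureIds) {
  inv <- function(map, keys, targetIds) {
    idx <- rep(list(integer()), length(targetIds))
    names(idx) <- targetIds
    for (i in seq_along(keys)) {
      tg <- map[[keys[i]]]
      if (is.null(tg)) next
      for (p in tg) idx[[p]] <- c(idx[[p]], i)
    }
    idx
  }
  l3ids <- h@levelIndex$l3; l2ids <- h@levelIndex$l2; l1ids <- h@levelIndex$l1
  list(
    l3 = inv(h@koToL3, featureIds, l3ids),
    l2 = inv(h@l3ToL2, l3ids, l2ids),
    l1 = inv(h@l2ToL1, l2ids, l1ids),
    uncovered = setdiff(featureIds, names(h@koToL3))
  )
}

.collapseVec <- function(x, idxList) {
  vapply(idxList, function(ii) sum(x[ii]), numeric(1L))
}

#' Collapse a gene-family profile onto one pathway level
#'
#' Each gene family's abundance is added to every pathway it annotates at
#' level 3; level-2 values are the sums of their level-3 children, and
#' likewise for level 1. A gene family feeding several pathways is counted
#' once per pathway, so collapsed vectors need not sum to 1. Gene families
#' absent from the hierarchy contribute nothing.
#'
#' @param x named non-negative numeric vector (gene-family profile,
#'   normally relative abundances).
#' @param h a \linkS4class{FunctionHierarchy}.
#' @param level target level: 3, 2 or 1.
#' @param warnUncovered warn (once) about gene families absent from the
#'   hierarchy; default `TRUE`.
#' @return named numeric vector aligned to `levelIds(h, level)`.
#' @examples
#' h <- functionHierarchy(list(K1 = c("P1", "P2"), K2 = "P2"),
#'                        list(P1 = "Q1", P2 = "Q1"), list(Q1 = "R1"))
#' collapseProfile(c(K1 = 0.6, K2 = 0.4), h, level = 3)
#' @export
collapseProfile <- function(x, h, level = 3, warnUncovered = TRUE) {
  stopifnot(is(h, "FunctionHierarchy"), level %in% c(1, 2, 3))
  if (is.null(names(x))) stop("profile vector must be named by gene family")
  if (any(x < 0)) stop("negative abundance entry")
  idx <- .levelIndexLists(h, names(x))
  if (warnUncovered && length(idx$uncovered))
    warning(length(idx$uncovered),
            " gene families absent from the hierarchy contribute nothing ",
            "at pathway levels: ",
            paste(utils::head(idx$uncovered, 10L), collapse = ", "),
            if (length(idx$uncovered) > 10L) ", ..." else "")
  v3 <- .collapseVec(x, idx$l3)
  if (level == 3) return(v3)
  v2 <- .collapseVec(v3, idx$l2)
  if (level == 2) return(v2)
  .collapseVec(v2, idx$l1)
}

.combineHms <- function(d0, d3, d2, d1, w) {
  (w@w0 * d0 + w@w3 * d3 + w@w2 * d2 + w@w1 * d1) / (w@w0 + w@w1 + w@w2 + w@w3)
}

#' Hierarchical dissimilarity between two functional profiles
#'
#' The weighted mean of Bray-Curtis distances computed at the gene-family
#' level and at pathway levels 3, 2 and 1 after collapsing through the
#' hierarchy:
#' `(w0*D0 + w3*D3 + w2*D2 + w1*D1) / (w0 + w1 + w2 + w3)`.
#' With the default weights (4, 3, 2, 1 for the gene-family level and
#' pathway levels 3, 2, 1) two profiles with disjoint gene families but
#' identical collapsed pathway profiles score 0.4 rather than the 1.0 a
#' flat metric reports.
#'
#' @param a,b named, feature-aligned, normalized gene-family profiles.
#' @param h a \linkS4class{FunctionHierarchy}.
#' @param w an \linkS4class{HmsWeights} (default [hmsWeights()]).
#' @return a number in `[0, 1]`.
#' @seealso [pairwiseDistances()] for whole-table computation.
#' @export
hmsDistance <- function(a, b, h, w = hmsWeights()) {
  stopifnot(is(h, "FunctionHierarchy"), is(w, "HmsWeights"))
  if (is.null(names(a)) || is.null(names(b)))
    stop("profiles must be named by gene family")
  if (!identical(names(a), names(b)))
    stop("profiles are not feature-aligned")
  idx <- .levelIndexLists(h, names(a))
  a3 <- .collapseVec(a, idx$l3); b3 <- .collapseVec(b, idx$l3)
  a2 <- .collapseVec(a3, idx$l2); b2 <- .collapseVec(b3, idx$l2)
  a1 <- .collapseVec(a2, idx$l1); b1 <- .collapseVec(b2, idx$l1)
  .combineHms(brayCurtis(a, b), brayCurtis(a3, b3),
              brayCurtis(a2, b2), brayCurtis(a1, b1), w)
}

## collapse every sample row of a matrix through one index list
.collapseRows <- function(M, idxList) {
  out <- matrix(0, nrow(M), length(idxList),
                dimnames = list(rownames(M), names(idxList)))
  for (i in seq_len(nrow(M))) out[i, ] <- .collapseVec(M[i, ], idxList)
  out
}

#' Pairwise distance matrix of a profile table
#'
#' Computes all `n(n-1)/2` upper-triangle pair distances, mirrors them to
#' the lower triangle and zeroes the diagonal. Pairs are enumerated
#' statically in row-major order and every pair is computed independently,
#' so the result is bit-identical for any `workers` value. Profiles are
#' normalized to relative abundance first (a no-op if already normalized).
#'
#' @param p a \linkS4class{ProfileTable}.
#' @param metric one of `"hms"`, `"bray_curtis"`, `"cosine"`,
#'   `"euclidean"`, `"jsd"`.
#' @param h a \linkS4class{FunctionHierarchy}; required for (and only used
#'   by) `metric = "hms"`.
#' @param w an \linkS4class{HmsWeights} for `metric = "hms"`.
#' @param workers number of parallel workers (forked; >1 has no effect on
#'   the values, only on wall time).
#' @return a \linkS4class{DistanceMatrix}.
#' @examples
#' sim <- simulateConvergentPathways(syntheticDesign(seed = 1))
#' d <- pairwiseDistances(sim$profiles, "hms", sim$hierarchy)
#' @export
pairwiseDistances <- function(p,
                              metric = c("hms", "bray_curtis", "cosine",
                                         "euclidean", "jsd"),
                              h = NULL, w = hmsWeights(), workers = 1L) {
  stopifnot(is(p, "ProfileTable"))
  metric <- match.arg(metric)
  workers <- as.integer(workers)
  if (workers < 1L) stop("workers must be a positive integer")
  if (!p@normalized) p <- normalizeProfiles(p)
  X <- abundances(p)
  n <- nrow(X)
  ids <- rownames(X)

  if (metric == "hms") {
    if (is.null(h)) stop("metric 'hms' requires a FunctionHierarchy")
    stopifnot(is(h, "FunctionHierarchy"), is(w, "HmsWeights"))
    idx <- .levelIndexLists(h, colnames(X))
    if (length(idx$uncovered))
      warning(length(idx$uncovered),
              " gene families absent from the hierarchy contribute nothing ",
              "at pathway levels: ",
              paste(utils::head(idx$uncovered, 10L), collapse = ", "),
              if (length(idx$uncovered) > 10L) ", ..." else "")
    L3 <- .collapseRows(X, idx$l3)
    L2 <- .collapseRows(L3, idx$l2)
    L1 <- .collapseRows(L2, idx$l1)
    pairFun <- function(i, j) {
      .combineHms(brayCurtis(X[i, ], X[j, ]), brayCurtis(L3[i, ], L3[j, ]),
                  brayCurtis(L2[i, ], L2[j, ]), brayCurtis(L1[i, ], L1[j, ]),
                  w)
    }
  } else {
    if (metric %in% c("cosine", "jsd")) {
      zs <- ids[rowSums(X) == 0]
      if (length(zs))
        stop("metric '", metric, "' is undefined for all-zero sample(s): ",
             paste(zs, collapse = ", "))
    }
    pairFun <- switch(metric,
      bray_curtis = function(i, j) brayCurtis(X[i, ], X[j, ]),
      cosine      = function(i, j) cosineDistance(X[i, ], X[j, ]),
      euclidean   = function(i, j) euclideanDistance(X[i, ], X[j, ]),
      jsd         = function(i, j) jensenShannon(X[i, ], X[j, ])
    )
  }

  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    rowFun <- function(i) vapply((i + 1L):n, function(j) pairFun(i, j),
                                 numeric(1L))
    rows <- if (workers > 1L) {
      parallel::mclapply(seq_len(n - 1L), rowFun, mc.cores = workers)
    } else {
      lapply(seq_len(n - 1L), rowFun)
    }
    for (i in seq_len(n - 1L)) {
      M[i, (i + 1L):n] <- rows[[i]]
      M[(i + 1L):n, i] <- rows[[i]]
    }
  }
  distanceMatrix(M)
}
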