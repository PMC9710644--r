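## Central S4 containers. All of them are plain in-memory value objects;
## constructors are the exported camelCase functions defined alongside.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' FunctionHierarchy: multi-level functional pathway annotation
#'
#' Maps gene families (e.g. KEGG Orthologs) onto a three-level metabolic
#' pathway hierarchy in the style of the KEGG BRITE classification:
#' gene family -> level-3 pathway -> level-2 pathway -> level-1 category.
#' Every link may be many-to-many, since a single gene family routinely
#' participates in several metabolic pathways.
#'
#' @slot koToL3 named list; for each gene family, the character vector of
#'   level-3 pathways it is annotated to.
#' @slot l3ToL2 named list; for each level-3 pathway, its level-2 parents.
#' @slot l2ToL1 named list; for each level-2 pathway, its level-1 parents.
#' @slot levelIndex list with elements `l3`, `l2`, `l1`: lexicographically
#'   sorted identifier vectors fixing the position of each pathway in
#'   collapsed abundance vectors.
#' @seealso [loadHierarchy()], [collapseProfile()]
#' @export
setClass("FunctionHierarchy",
  representation(
    koToL3 = "list",
    l3ToL2 = "list",
    l2ToL1 = "list",
    levelIndex = "list"
  )
)

setValidity("FunctionHierarchy", function(object) {
  msg <- character()
  chkmap <- function(m, what) {
    if (length(m) == 0L) return(character())
    out <- character()
    if (is.null(names(m)) || anyDuplicated(names(m)))
      out <- c(out, paste0(what, ": keys must be unique and named"))
    if (any(vapply(m, length, 0L) == 0L))
      out <- c(out, paste0(what, ": every key needs a non-empty mapping set"))
    out
  }
  msg <- c(msg, chkmap(object@koToL3, "koToL3"),
           chkmap(object@l3ToL2, "l3ToL2"),
           chkmap(object@l2ToL1, "l2ToL1"))
  orphan3 <- setdiff(unique(unlist(object@koToL3)), names(object@l3ToL2))
  if (length(orphan3))
    msg <- c(msg, paste0("dangling level-3 references (no parent entry): ",
                         paste(orphan3, collapse = ", ")))
  orphan2 <- setdiff(unique(unlist(object@l3ToL2)), names(object@l2ToL1))
  if (length(orphan2))
    msg <- c(msg, paste0("dangling level-2 references (no parent entry): ",
                         paste(orphan2, collapse = ", ")))
  for (lv in c("l3", "l2", "l1")) {
    idx <- object@levelIndex[[lv]]
    if (anyDuplicated(idx))
      msg <- c(msg, paste0("levelIndex$", lv, " contains duplicates"))
  }
  want <- list(
    l3 = sort(unique(as.character(c(names(object@l3ToL2), unlist(object@koToL3))))),
    l2 = sort(unique(as.character(c(names(object@l2ToL1), unlist(object@l3ToL2))))),
    l1 = sort(unique(as.character(unlist(object@l2ToL1))))
  )
  for (lv in c("l3", "l2", "l1")) {
    if (!identical(sort(as.character(object@levelIndex[[lv]])), want[[lv]]))
      msg <- c(msg, paste0("levelIndex$", lv,
                           " does not cover exactly the identifiers of that level"))
  }
  if (length(msg)) msg else TRUE
})

#' ProfileTable: samples x gene-family abundance matrix
#'
#' Functional profiles of a set of microbiome samples: one row per sample,
#' one column per gene family, non-negative abundances. After
#' [normalizeProfiles()] each non-degenerate row sums to one (relative
#' abundance); all-zero rows are left untouched and recorded in
#' `zeroSamples`.
#'
#' @slot abundance numeric matrix, samples x features, with dimnames.
#' @slot normalized logical; `TRUE` once rows are relative abundances.
#' @slot zeroSamples character; identifiers of all-zero samples found
#'   during normalization (`NULL` before normalization).
#' @seealso [readProfileTable()], [pairwiseDistances()]
#' @export
setClass("ProfileTable",
  representation(
    abundance = "matrix",
    normalized = "logical",
    zeroSamples = "characterOrNULL"
  ),
  prototype(normalized = FALSE, zeroSamples = NULL)
)

setValidity("ProfileTable", function(object) {
  a <- object@abundance
  msg <- character()
  if (!is.numeric(a)) msg <- c(msg, "abundance must be numeric")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "abundance needs sample rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicate sample identifiers")
    if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicate feature identifiers")
  }
  if (is.numeric(a) && length(a) && any(!is.finite(a)))
    msg <- c(msg, "abundance contains non-finite values")
  if (is.numeric(a) && length(a) && any(a < 0))
    msg <- c(msg, "abundance contains negative values")
  if (isTRUE(object@normalized) && is.numeric(a) && nrow(a)) {
    rs <- rowSums(a)
    bad <- abs(rs - 1) > 1e-9 & rs != 0
    if (any(bad))
      msg <- c(msg, "normalized rows must sum to 1 (within 1e-9) or be all-zero")
  }
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: labelled symmetric pairwise dissimilarities
#'
#' @slot values numeric n x n matrix with identical row/column sample
#'   labels, exactly symmetric, zero diagonal, non-negative entries.
#' @seealso [pairwiseDistances()], [readDistanceMatrix()]
#' @export
setClass("DistanceMatrix", representation(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column sample labels must be present and identical")
  else if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate sample identifiers")
  if (is.numeric(v) && nrow(v) == ncol(v) && length(v)) {
    if (!identical(v, t(v))) msg <- c(msg, "matrix must be exactly symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' PcoaResult: principal-coordinates embedding of a distance matrix
#'
#' @slot coordinates numeric n x k matrix (sample rownames, axis colnames);
#'   axis j is the j-th eigenvector scaled by the square root of its
#'   eigenvalue.
#' @slot eigenvalues retained positive eigenvalues, non-increasing.
#' @slot explained eigenvalue share of the positive-eigenvalue total.
#' @slot nNegative number of negative eigenvalues that were discarded
#'   (non-Euclidean input produces them).
#' @seealso [pcoa()], [writePcoa()]
#' @export
setClass("PcoaResult",
  representation(
    coordinates = "matrix",
    eigenvalues = "numeric",
    explained = "numeric",
    nNegative = "integer"
  )
)

setValidity("PcoaResult", function(object) {
  msg <- character()
  k <- ncol(object@coordinates)
  if (length(object@eigenvalues) != k || length(object@explained) != k)
    msg <- c(msg, "eigenvalues/explained must match the number of axes")
  if (k > 1 && any(diff(object@eigenvalues) > 1e-12))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (sum(object@explained) > 1 + 1e-9)
    msg <- c(msg, "explained proportions must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' HmsWeights: per-level weights of the hierarchical dissimilarity
#'
#' The hierarchical dissimilarity is the weighted mean of Bray-Curtis
#' distances at the gene-family level (weight `w0`) and at pathway levels
#' 1-3 (weights `w1`, `w2`, `w3`). Defaults give the gene-family level the
#' largest weight (4, its resolution is highest) and weight each pathway
#' level by its depth (level i gets weight i).
#'
#' @slot w0,w1,w2,w3 non-negative reals, not all zero.
#' @seealso [hmsWeights()], [hmsDistance()]
#' @export
setClass("HmsWeights",
  representation(w0 = "numeric", w1 = "numeric", w2 = "numeric", w3 = "numeric")
)

setValidity("HmsWeights", function(object) {
  w <- c(object@w0, object@w1, object@w2, object@w3)
  if (length(w) != 4L || any(!is.finite(w))) return("weights must be four finite numbers")
  if (any(w < 0)) return("weights must be non-negative")
  if (sum(w) == 0) return("at least one weight must be positive")
  TRUE
})

#' SyntheticDesign: parameters of the synthetic profile generators
#'
#' @slot nPerGroup samples per group (three groups are generated).
#' @slot noise within-group multiplicative perturbation scale: each base
#'   abundance is multiplied by `1 + u`, `u ~ Uniform(-noise, noise)`.
#' @slot sparsity expected fraction of zeroed cells per sample (used by
#'   the sparse design only).
#' @slot seed integer seed governing all randomness of a generator call.
#' @seealso [syntheticDesign()], [simulateConvergentPathways()],
#'   [simulateSparseProfiles()]
#' @export
setClass("SyntheticDesign",
  representation(
    nPerGroup = "integer",
    noise = "numeric",
    sparsity = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be at least 2")
  if (object@noise < 0) msg <- c(msg, "noise must be non-negative")
  if (object@sparsity < 0 || object@sparsity >= 1)
    msg <- c(msg, "sparsity must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

## ---- accessors & show -------------------------------------------------

#' @describeIn ProfileTable sample identifiers
#' @export
setMethod("sampleNames", "ProfileTable", function(x) rownames(x@abundance))

#' @describeIn ProfileTable feature identifiers
#' @export
setMethod("featureNames", "ProfileTable", function(x) colnames(x@abundance))

#' @describeIn ProfileTable the abundance matrix
#' @export
setMethod("abundances", "ProfileTable", function(x) x@abundance)

#' @describeIn ProfileTable dimensions (samples, features)
#' @param x a ProfileTable
#' @export
setMethod("dim", "ProfileTable", function(x) dim(x@abundance))

#' @describeIn DistanceMatrix sample identifiers
#' @export
setMethod("sampleNames", "DistanceMatrix", function(x) rownames(x@values))

#' @describeIn PcoaResult sample identifiers
#' @export
setMethod("sampleNames", "PcoaResult", function(x) rownames(x@coordinates))

#' @describeIn DistanceMatrix coerce to a base matrix
#' @param x a DistanceMatrix
#' @param ... ignored
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' Coerce a DistanceMatrix to a stats::dist object
#'
#' @param m a \linkS4class{DistanceMatrix}.
#' @param diag,upper passed to [stats::as.dist()].
#' @return a `dist` object.
#' @export
as.dist.DistanceMatrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m@values, diag = diag, upper = upper)
}

setMethod("show", "FunctionHierarchy", function(object) {
  cat("FunctionHierarchy:", length(object@koToL3), "gene families;",
      length(object@levelIndex$l3), "level-3,",
      length(object@levelIndex$l2), "level-2,",
      length(object@levelIndex$l1), "level-1 pathways\n")
})

setMethod("show", "ProfileTable", function(object) {
  cat("ProfileTable:", nrow(object@abundance), "samples x",
      ncol(object@abundance), "features;",
      if (object@normalized) "relative abundance" else "raw", "\n")
  if (length(object@zeroSamples))
    cat("  all-zero samples:", paste(object@zeroSamples, collapse = ", "), "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix:", nrow(object@values), "samples\n")
})

setMethod("show", "PcoaResult", function(object) {
  cat("PcoaResult:", nrow(object@coordinates), "samples on",
      ncol(object@coordinates), "axes\n")
  if (length(object@explained))
    cat("  explained:", paste(sprintf("%.1f%%", 100 * object@explained),
                              collapse = " "), "\n")
  if (object@nNegative > 0L)
    cat("  discarded", object@nNegative, "negative eigenvalues\n")
})

setMethod("show", "HmsWeights", function(object) {
  cat(sprintf("HmsWeights: w0=%g (gene family), w3=%g, w2=%g, w1=%g\n",
              object@w0, object@w3, object@w2, object@w1))
})

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    "SyntheticDesign: 3 x %d samples, noise=%g, sparsity=%g, seed=%d\n",
    object@nPerGroup, object@noise, object@sparsity, object@seed))
})

## ---- constructors -----------------------------------------------------

#' Construct an HmsWeights object
#'
#' @param w0 weight of the gene-family (KO) level; default 4.
#' @param w1,w2,w3 weights of pathway levels 1, 2 and 3; defaults 1, 2, 3.
#' @return an \linkS4class{HmsWeights} object.
#' @examples
#' hmsWeights()              # defaults: KO level 4, pathway level i weight i
#' hmsWeights(w1 = 0, w2 = 0, w3 = 0)  # reduces HMS to plain Bray-Curtis
#' @export
hmsWeights <- function(w0 = 4, w1 = 1, w2 = 2, w3 = 3) {
  new("HmsWeights", w0 = as.numeric(w0), w1 = as.numeric(w1),
      w2 = as.numeric(w2), w3 = as.numeric(w3))
}

#' Construct a SyntheticDesign
#'
#' @param nPerGroup samples per group (default 10; three groups -> 30
#'   samples).
#' @param noise within-group multiplicative perturbation scale (default
#'   0.1, i.e. subtle abundance variation).
#' @param sparsity expected per-sample fraction of zeroed cells for the
#'   sparse design (default 0.6).
#' @param seed integer seed (default 1).
#' @return a \linkS4class{SyntheticDesign} object.
#' @export
syntheticDesign <- function(nPerGroup = 10, noise = 0.1, sparsity = 0.6,
                            seed = 1) {
  new("SyntheticDesign", nPerGroup = as.integer(nPerGroup),
      noise = as.numeric(noise), sparsity = as.numeric(sparsity),
      seed = as.integer(seed))
}

#' Construct a ProfileTable from a samples x features matrix
#'
#' @param abundance numeric matrix, samples as rows, features as columns,
#'   with row and column names.
#' @param normalized logical; set `TRUE` only if rows are already relative
#'   abundances.
#' @param zeroSamples identifiers of all-zero samples (normally set by
#'   [normalizeProfiles()]).
#' @return a \linkS4class{ProfileTable}.
#' @export
profileTable <- function(abundance, normalized = FALSE, zeroSamples = NULL) {
  storage.mode(abundance) <- "double"
  new("ProfileTable", abundance = abundance, normalized = normalized,
      zeroSamples = zeroSamples)
}

#' Construct a DistanceMatrix from a square symmetric matrix
#'
#' @param values numeric square matrix with matching row/column labels,
#'   symmetric with a zero diagonal.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
distanceMatrix <- function(values) {
  storage.mode(values) <- "double"
  new("DistanceMatrix", values = values)
}

#' Construct a FunctionHierarchy from its three mapping lists
#'
#' The level index (identifier ordering of each level) is derived
#' automatically and sorted lexicographically, so collapsed vectors are
#' reproducible regardless of input row order.
#'
#' @param koToL3 named list: gene family -> character vector of level-3
#'   pathways.
#' @param l3ToL2 named list: level-3 pathway -> level-2 parents.
#' @param l2ToL1 named list: level-2 pathway -> level-1 parents.
#' @return a \linkS4class{FunctionHierarchy}.
#' @examples
#' functionHierarchy(
#'   koToL3 = list(K1 = c("P1", "P2"), K2 = "P2"),
#'   l3ToL2 = list(P1 = "Q1", P2 = "Q1"),
#'   l2ToL1 = list(Q1 = "R1"))
#' @export
functionHierarchy <- function(koToL3 = list(), l3ToL2 = list(),
                              l2ToL1 = list()) {
  canon <- function(m) {
    m <- lapply(m, function(v) sort(unique(as.character(v))))
    if (length(m)) m[order(names(m))] else m
  }
  koToL3 <- canon(koToL3); l3ToL2 <- canon(l3ToL2); l2ToL1 <- canon(l2ToL1)
  levelIndex <- list(
    l3 = sort(unique(c(names(l3ToL2), unlist(koToL3)))),
    l2 = sort(unique(c(names(l2ToL1), unlist(l3ToL2)))),
    l1 = sort(unique(unlist(l2ToL1)))
  )
  levelIndex <- lapply(levelIndex, function(v) if (is.null(v)) character() else v)
  new("FunctionHierarchy", koToL3 = koToL3, l3ToL2 = l3ToL2,
      l2ToL1 = l2ToL1, levelIndex = levelIndex)
}
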