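## Group-separation statistics on distance matrices.

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix.
#' All `n(n-1)/2` pairwise distances are ranked (ties get average ranks)
#' and `R = (rB - rW) / (M/2)` with `rB`/`rW` the mean rank of
#' between-/within-group pairs and `M = n(n-1)/2`. `R` is close to 1 when
#' between-group distances dominate, near 0 without structure, and is
#' invariant to any order-preserving transform of the distances. The
#' p-value permutes group labels:
#' `p = (1 + #{R_perm >= R_obs}) / (1 + permutations)`.
#'
#' @param d a \linkS4class{DistanceMatrix} (or symmetric labelled matrix).
#' @param grouping factor or character vector of group labels; if named,
#'   it is reordered to match `sampleNames(d)`, otherwise it must already
#'   be aligned. At least two groups, each with at least two members.
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation generator (default 1).
#' @return list with `R`, `pValue` and `permutations`.
#' @export
anosimTest <- function(d, grouping, permutations = 999, seed = 1) {
  if (is(d, "DistanceMatrix")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (!is.null(names(grouping))) {
    ids <- rownames(d)
    if (is.null(ids) || !all(ids %in% names(grouping)))
      stop("grouping names do not cover the samples of the distance matrix")
    grouping <- grouping[ids]
  }
  g <- factor(as.character(grouping))
  if (length(g) != n) stop("grouping length must equal the number of samples")
  if (nlevels(g) < 2L) stop("ANOSIM needs at least two groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least two members; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  lower <- lower.tri(d)
  rk <- rank(d[lower])          # average ranks for ties
  M <- length(rk)
  statR <- function(gg) {
    within <- outer(gg, gg, "==")[lower]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  obs <- statR(g)
  permutations <- as.integer(permutations)
  if (permutations < 1L) stop("permutations must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(permutations)) {
    if (statR(g[sample.int(n)]) >= obs) exceed <- exceed + 1L
  }
  list(R = obs,
       pValue = (1 + exceed) / (1 + permutations),
       permutations = permutations)
}

#' Read sample group labels from a metadata file
#'
#' Tab-separated, two columns `sample_id <TAB> group`, header line
#' required.
#'
#' @param path path to the metadata file.
#' @return factor of group labels, named by sample identifier.
#' @export
readGroupLabels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("metadata needs columns sample_id and group")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample identifiers in ", path)
  stats::setNames(factor(df[[2L]]), df[[1L]])
}

#' Write sample group labels
#'
#' @param grouping factor/character named by sample identifier.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroupLabels <- function(grouping, path) {
  stopifnot(!is.null(names(grouping)))
  writeLines(c("sample_id\tgroup",
               paste(names(grouping), as.character(grouping), sep = "\t")),
             path)
  invisible(path)
}
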