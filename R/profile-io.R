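## Tab-separated readers/writers for profile tables and distance matrices.
## Profile tables default to the HUMAnN2/PICRUSt2 export convention:
## features as rows, samples as columns.

.readTsvMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, quote = "", comment.char = "",
                          colClasses = "character")
  m <- as.matrix(df)
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in ", path, " at row '", rownames(m)[bad[1L]],
         "', column '", colnames(m)[bad[2L]], "'")
  }
  m
}

#' Read a functional profile table
#'
#' Reads a tab-separated abundance table and returns it in samples x
#' features orientation. The default layout is features as rows and
#' samples as columns (the common profiler export convention); set
#' `orientation = "samples_as_rows"` for the transposed layout. Values are
#' taken as given -- call [normalizeProfiles()] to convert to relative
#' abundance.
#'
#' @param path path to the table; first row and first column hold
#'   identifiers.
#' @param orientation `"features_as_rows"` (default) or
#'   `"samples_as_rows"`.
#' @return a \linkS4class{ProfileTable} (not yet normalized).
#' @export
readProfileTable <- function(path,
                             orientation = c("features_as_rows",
                                             "samples_as_rows")) {
  orientation <- match.arg(orientation)
  m <- .readTsvMatrix(path)
  if (orientation == "features_as_rows") m <- t(m)
  if (any(m < 0)) stop("negative abundance in ", path)
  profileTable(m)
}

#' Write a profile table
#'
#' @param p a \linkS4class{ProfileTable}.
#' @param path output path.
#' @param orientation layout to write, as in [readProfileTable()].
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(p, path,
                              orientation = c("features_as_rows",
                                              "samples_as_rows")) {
  stopifnot(is(p, "ProfileTable"))
  orientation <- match.arg(orientation)
  m <- abundances(p)
  if (orientation == "features_as_rows") {
    m <- t(m)
    corner <- "#feature"
  } else corner <- "#sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(corner, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Normalize profiles to relative abundance
#'
#' Divides every sample row with a positive total by its sum. All-zero
#' rows are left unchanged, recorded in the `zeroSamples` slot and
#' reported with a warning. The operation is idempotent.
#'
#' @param p a \linkS4class{ProfileTable}.
#' @return a normalized \linkS4class{ProfileTable}.
#' @export
normalizeProfiles <- function(p) {
  stopifnot(is(p, "ProfileTable"))
  m <- abundances(p)
  rs <- rowSums(m)
  zero <- rownames(m)[rs == 0]
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  if (length(zero))
    warning("all-zero sample(s) left unnormalized: ",
            paste(zero, collapse = ", "))
  profileTable(m, normalized = TRUE, zeroSamples = if (length(zero)) zero else NULL)
}

#' Merge profile tables over the union of their features
#'
#' Features absent from one table are zero-filled, so profiles produced
#' per-run or per-study can be combined before distance computation.
#'
#' @param ... \linkS4class{ProfileTable} objects (or a single list of
#'   them).
#' @return a \linkS4class{ProfileTable} holding all samples; not
#'   normalized.
#' @export
mergeProfileTables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is(tabs[[1L]], "ProfileTable"))
    tabs <- tabs[[1L]]
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, is, TRUE, "ProfileTable")))
  feats <- sort(unique(unlist(lapply(tabs, featureNames))))
  rows <- lapply(tabs, function(p) {
    m <- matrix(0, nrow(abundances(p)), length(feats),
                dimnames = list(sampleNames(p), feats))
    m[, featureNames(p)] <- abundances(p)
    m
  })
  profileTable(do.call(rbind, rows))
}

#' Read a square distance matrix
#'
#' Reads a tab-separated square table with identical row/column sample
#' labels. Asymmetries beyond `1e-8` are an error; smaller serialization
#' noise is removed by mirroring the upper triangle, so the stored matrix
#' is exactly symmetric.
#'
#' @param path path to the matrix file.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
readDistanceMatrix <- function(path) {
  m <- .readTsvMatrix(path)
  if (nrow(m) != ncol(m))
    stop("distance matrix must be square: ", nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("row and column sample labels disagree in ", path)
  if (nrow(m) && max(abs(m - t(m))) > 1e-8)
    stop("matrix is asymmetric beyond 1e-8 in ", path)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  distanceMatrix(m)
}

#' Write a distance matrix
#'
#' Serializes the full square table, tab-separated, with values rounded to
#' six decimal digits.
#'
#' @param d a \linkS4class{DistanceMatrix}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(d, path) {
  stopifnot(is(d, "DistanceMatrix"))
  m <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#sample", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(formatC(r, format = "f", digits = 6), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}
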