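## Classical (metric) multidimensional scaling via Gower double
## centering, plus a Monte-Carlo Procrustes test for comparing two
## ordinations.

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers the element-wise squared distance matrix
#' (`B = -1/2 * J D^2 J`, `J = I - 11'/n`), eigendecomposes `B` and scales
#' the top-`k` positive eigenvectors by the square roots of their
#' eigenvalues. Axes are ordered by decreasing eigenvalue. Negative
#' eigenvalues -- routine for Bray-Curtis-derived matrices, which are not
#' Euclidean-embeddable -- are discarded and counted; no Lingoes/Cailliez
#' correction is applied. The sign of each axis is fixed so that its
#' largest-magnitude loading is positive (ties broken by lowest sample
#' index), making coordinates reproducible.
#'
#' @param d a \linkS4class{DistanceMatrix} (or plain symmetric matrix with
#'   sample labels and zero diagonal).
#' @param k number of axes to retain (positive, at most `n - 1`; default
#'   3). If fewer than `k` positive eigenvalues exist, all positive axes
#'   are returned with a warning.
#' @return a \linkS4class{PcoaResult}. Explained proportions are relative
#'   to the sum of positive eigenvalues.
#' @export
pcoa <- function(d, k = 3) {
  if (is(d, "DistanceMatrix")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (k >= n) stop("k must be smaller than the number of samples (", n, ")")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))

  A <- -0.5 * d^2
  rm_ <- rowMeans(A); gm <- mean(A)
  B <- A - outer(rm_, rm_, "+") + gm  # rowMeans == colMeans (symmetric d)
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-9
  pos <- which(e$values > tol)
  nNeg <- sum(e$values < -tol)

  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalues; k reduced from ",
            k, " to ", length(pos))
    k <- length(pos)
  }
  keep <- pos[seq_len(k)]
  vals <- e$values[keep]
  coords <- e$vectors[, keep, drop = FALSE] *
    rep(sqrt(vals), each = n)
  ## sign convention: largest-|loading| entry of each axis is positive
  for (j in seq_len(ncol(coords))) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(ids, if (k) paste0("PC", seq_len(k)))
  totPos <- sum(e$values[pos])
  new("PcoaResult",
      coordinates = coords,
      eigenvalues = vals,
      explained = if (k) vals / totPos else numeric(),
      nNegative = as.integer(nNeg))
}

#' Write PCoA coordinates
#'
#' Tab-separated: two comment lines carrying the eigenvalues and
#' explained proportions, then one row per sample
#' (`sample_id <TAB> PC1 <TAB> ... <TAB> PCk`).
#'
#' @param res a \linkS4class{PcoaResult}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePcoa <- function(res, path) {
  stopifnot(is(res, "PcoaResult"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(format(v, digits = 12, trim = TRUE), collapse = " ")
  writeLines(c(paste("# eigenvalues:", fmt(res@eigenvalues)),
               paste("# explained:", fmt(res@explained))), con)
  writeLines(paste(c("#sample", colnames(res@coordinates)), collapse = "\t"),
             con)
  body <- apply(res@coordinates, 1L, function(r)
    paste(format(r, digits = 12, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(res@coordinates), body, sep = "\t"), con)
  invisible(path)
}

#' Read PCoA coordinates written by [writePcoa()]
#'
#' @param path path to a coordinates file.
#' @return numeric samples x axes matrix with sample rownames.
#' @export
readPcoa <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("no coordinate rows in ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1L])))
  rownames(m) <- ids
  colnames(m) <- paste0("PC", seq_len(ncol(m)))
  m
}

#' Monte-Carlo Procrustes comparison of two configurations
#'
#' Measures the agreement of two point configurations over the same
#' samples after optimal translation, rotation and scaling (symmetric
#' Procrustes). Both configurations are column-centered and scaled to
#' unit total sum of squares; the correlation is the sum of singular
#' values of `A'B`, which is 1 exactly when the shapes coincide. The
#' p-value permutes the row order of `B`:
#' `p = (1 + #{perm >= observed}) / (1 + permutations)`.
#'
#' @param A,B numeric matrices with one row per sample (rows must
#'   correspond), or \linkS4class{PcoaResult} objects. If the axis counts
#'   differ, the narrower matrix is padded with zero columns.
#' @param permutations number of row permutations (default 999).
#' @param seed integer seed for the permutation generator (default 1).
#' @return list with `correlation`, `pValue` and `permutations`.
#' @export
procrustesTest <- function(A, B, permutations = 999, seed = 1) {
  if (is(A, "PcoaResult")) A <- A@coordinates
  if (is(B, "PcoaResult")) B <- B@coordinates
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B))
    stop("configurations have different numbers of rows: ",
         nrow(A), " vs ", nrow(B))
  k <- max(ncol(A), ncol(B))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  prep <- function(M) {
    M <- pad(M)
    M <- sweep(M, 2L, colMeans(M))
    ss <- sum(M^2)
    if (ss == 0) stop("degenerate configuration: zero total sum of squares")
    M / sqrt(ss)
  }
  A <- prep(A); B <- prep(B)
  corrOf <- function(Bm) sum(svd(crossprod(A, Bm))$d)
  obs <- corrOf(B)
  permutations <- as.integer(permutations)
  if (permutations < 1L) stop("permutations must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(B)
  exceed <- 0L
  for (i in seq_len(permutations)) {
    Bp <- B[sample.int(n), , drop = FALSE]
    Bp <- sweep(Bp, 2L, colMeans(Bp))  # centering is permutation-invariant
    if (corrOf(Bp) >= obs) exceed <- exceed + 1L
  }
  list(correlation = obs,
       pValue = (1 + exceed) / (1 + permutations),
       permutations = permutations)
}
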