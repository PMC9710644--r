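## Hierarchy annotation file format: tab-separated, four columns
##   gene_family <TAB> level3 <TAB> level2 <TAB> level1
## one row per (gene family, level-3 pathway) membership, carrying that
## pathway's parent chain; lines starting with '#' are comments/header.

#' Load a functional hierarchy annotation file
#'
#' Reads a four-column tab-separated annotation
#' (`gene_family  level3  level2  level1`, one row per gene-family /
#' level-3-pathway membership with its parent chain) into a
#' \linkS4class{FunctionHierarchy}. Duplicate rows are merged; row order
#' never affects the result. Lines starting with `#` are skipped.
#'
#' @param path path to the annotation file.
#' @return a \linkS4class{FunctionHierarchy}.
#' @examples
#' demo <- system.file("extdata", "demo_hierarchy.tsv", package = "hmsdiv")
#' loadHierarchy(demo)
#' @export
loadHierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(functionHierarchy())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- lineno[nf != 4L][1L]
    stop("malformed hierarchy row at line ", bad,
         ": expected 4 tab-separated columns, found ", nf[nf != 4L][1L])
  }
  m <- do.call(rbind, fields)
  if (any(m == "")) {
    bad <- lineno[apply(m == "", 1L, any)][1L]
    stop("malformed hierarchy row at line ", bad, ": empty field")
  }
  functionHierarchy(
    koToL3 = split(m[, 2L], m[, 1L]),
    l3ToL2 = split(m[, 3L], m[, 2L]),
    l2ToL1 = split(m[, 4L], m[, 3L])
  )
}

#' Serialize a FunctionHierarchy back to the annotation format
#'
#' Expands the three mapping lists into four-column rows (one per
#' gene-family/level-3 membership and parent combination). A
#' write-then-load round trip reproduces the hierarchy exactly.
#'
#' @param h a \linkS4class{FunctionHierarchy}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHierarchy <- function(h, path) {
  stopifnot(is(h, "FunctionHierarchy"))
  rows <- character()
  for (ko in names(h@koToL3)) {
    for (p3 in h@koToL3[[ko]]) {
      for (p2 in h@l3ToL2[[p3]]) {
        for (p1 in h@l2ToL1[[p2]]) {
          rows <- c(rows, paste(ko, p3, p2, p1, sep = "\t"))
        }
      }
    }
  }
  writeLines(c("#gene_family\tlevel3\tlevel2\tlevel1", rows), path)
  invisible(path)
}

#' Partition features by hierarchy coverage
#'
#' Splits a set of gene-family identifiers into those annotated in the
#' hierarchy and those absent from it. Uncovered features still take part
#' in gene-family-level distances but contribute nothing at pathway
#' levels.
#'
#' @param h a \linkS4class{FunctionHierarchy}.
#' @param features character vector of gene-family identifiers.
#' @return list with character vectors `covered` and `uncovered`
#'   (disjoint; their union is `unique(features)`).
#' @export
hierarchyCoverage <- function(h, features) {
  stopifnot(is(h, "FunctionHierarchy"))
  features <- unique(as.character(features))
  hit <- features %in% names(h@koToL3)
  list(covered = features[hit], uncovered = features[!hit])
}

#' Pathway identifiers at one hierarchy level
#'
#' @param h a \linkS4class{FunctionHierarchy}.
#' @param level 3, 2 or 1.
#' @return character vector in the stable (lexicographic) level order used
#'   for collapsed vectors.
#' @export
levelIds <- function(h, level) {
  stopifnot(is(h, "FunctionHierarchy"), level %in% c(1, 2, 3))
  h@levelIndex[[paste0("l", level)]]
}
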