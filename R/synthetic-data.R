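## Synthetic profile generators. Each reproduces one designed failure
## mode of flat (gene-family-overlap) metrics: convergent pathways with
## divergent gene families, and sparse zero-inflated profiles. Both emit
## three groups (m1, m2, m3) of nPerGroup samples, a matching hierarchy
## and group labels, and are fully determined by the design seed.

.perturb <- function(base, noise) base * (1 + stats::runif(length(base), -noise, noise))

#' Simulate the convergent-pathways design (three groups, dense profiles)
#'
#' Groups are built so that gene-family overlap and pathway-level
#' similarity point in opposite directions: m1 shares 2 gene families
#' with m2 but only 1 with m3, yet the gene families of m1 and m3 collapse
#' onto exactly the same five level-3 pathways with matched abundances,
#' while m1 and m2 share only 2 of 5 level-3 pathways (and diverge at
#' levels 2 and 1). A flat metric therefore calls m1 closer to m2; the
#' hierarchical dissimilarity calls m1 closer to m3, which is the
#' metabolically correct reading. Within a group, each sample is the
#' group base composition perturbed multiplicatively by `noise` and
#' renormalized.
#'
#' Structure (fixed): 12 gene families, 8 level-3 pathways in two branches
#' (P01-P05 under Q1/R1, P06-P08 under Q2/R2); each group base spreads
#' relative abundance 0.2 over its 5 gene families.
#'
#' @param design a \linkS4class{SyntheticDesign}; `sparsity` is unused
#'   here.
#' @return list with `profiles` (normalized \linkS4class{ProfileTable}),
#'   `hierarchy` (\linkS4class{FunctionHierarchy}) and `groups` (factor
#'   named by sample).
#' @export
simulateConvergentPathways <- function(design = syntheticDesign()) {
  stopifnot(is(design, "SyntheticDesign"))
  set.seed(design@seed)

  ko <- sprintf("K%05d", 1:12)
  ko2l3 <- stats::setNames(as.list(sprintf("P%02d", c(1:5, 1, 2, 4, 5, 6:8))), ko)
  l3ToL2 <- stats::setNames(as.list(rep(c("Q1", "Q2"), c(5L, 3L))),
                            sprintf("P%02d", 1:8))
  l2ToL1 <- list(Q1 = "R1", Q2 = "R2")
  h <- functionHierarchy(ko2l3, l3ToL2, l2ToL1)

  groupKos <- list(
    m1 = ko[1:5],                 # -> P01..P05
    m2 = ko[c(1, 2, 10, 11, 12)], # shares K1,K2 with m1; -> P01,P02,P06..P08
    m3 = ko[c(3, 6, 7, 8, 9)]     # shares K3 with m1;   -> P01..P05 again
  )
  X <- matrix(0, 3L * design@nPerGroup, length(ko),
              dimnames = list(character(3L * design@nPerGroup), ko))
  labels <- character(nrow(X))
  r <- 0L
  for (grp in names(groupKos)) {
    for (i in seq_len(design@nPerGroup)) {
      r <- r + 1L
      v <- .perturb(rep(0.2, 5L), design@noise)
      X[r, groupKos[[grp]]] <- v / sum(v)
      rownames(X)[r] <- sprintf("%s_s%02d", grp, i)
      labels[r] <- grp
    }
  }
  list(profiles = profileTable(X, normalized = TRUE),
       hierarchy = h,
       groups = stats::setNames(factor(labels), rownames(X)))
}

#' Simulate the sparse zero-inflated design (three groups)
#'
#' Groups have nearly disjoint gene-family pools (m1 and m2 share 8 of 60
#' pool members, m3 shares none), but the pools of m1 and m2 annotate the
#' same level-3/2/1 pathway branch while m3 occupies a separate branch,
#' so every metric should call m1 closer to m2 than to m3. Group m3 is
#' the extreme-sparsity group: its pool is partitioned into disjoint
#' 6-gene-family blocks, one per sample, so within-group supports never
#' overlap and flat overlap-counting metrics saturate at their maxima
#' (all within-m3 Bray-Curtis distances are exactly 1, collapsing the
#' group to a point); the hierarchical dissimilarity still resolves
#' within-m3 variation through the shared pathway branch. Each cell is
#' perturbed by `noise` and zeroed independently with probability
#' `sparsity` before renormalization; a sample left all-zero is redrawn
#' (at most 100 attempts).
#'
#' @param design a \linkS4class{SyntheticDesign}; `sparsity` must be
#'   positive.
#' @return list with `profiles`, `hierarchy`, `groups` as in
#'   [simulateConvergentPathways()].
#' @export
simulateSparseProfiles <- function(design = syntheticDesign()) {
  stopifnot(is(design, "SyntheticDesign"))
  if (design@sparsity <= 0)
    stop("the sparse design requires sparsity > 0")
  set.seed(design@seed)
  n <- design@nPerGroup

  poolM1 <- sprintf("KA%03d", 1:60)
  poolM2 <- c(poolM1[1:8], sprintf("KB%03d", 1:52))  # 8 shared gene families
  poolM3 <- sprintf("KC%03d", seq_len(6L * n))       # disjoint branch
  branchA <- unique(c(poolM1, poolM2))
  ko2l3 <- c(
    stats::setNames(as.list(rep(sprintf("PA%d", 1:5), length.out = length(branchA))),
                    branchA),
    stats::setNames(as.list(rep(sprintf("PB%d", 1:5), length.out = length(poolM3))),
                    poolM3)
  )
  l3ToL2 <- list(PA1 = "QA1", PA2 = "QA1", PA3 = "QA2", PA4 = "QA2",
                 PA5 = "QA2", PB1 = "QB1", PB2 = "QB1", PB3 = "QB2",
                 PB4 = "QB2", PB5 = "QB2")
  l2ToL1 <- list(QA1 = "RA", QA2 = "RA", QB1 = "RB", QB2 = "RB")
  h <- functionHierarchy(ko2l3, l3ToL2, l2ToL1)

  feats <- sort(unique(c(poolM1, poolM2, poolM3)))
  drawSample <- function(pool) {
    for (attempt in 1:100) {
      v <- .perturb(rep(1, length(pool)), design@noise)
      v[stats::runif(length(pool)) < design@sparsity] <- 0
      if (any(v > 0)) {
        out <- stats::setNames(numeric(length(feats)), feats)
        out[pool] <- v / sum(v)
        return(out)
      }
    }
    stop("sample remained all-zero after 100 zero-inflation attempts; ",
         "lower sparsity")
  }

  X <- matrix(0, 3L * n, length(feats),
              dimnames = list(character(3L * n), feats))
  labels <- character(nrow(X))
  r <- 0L
  for (i in seq_len(n)) {
    r <- r + 1L; X[r, ] <- drawSample(poolM1)
    rownames(X)[r] <- sprintf("m1_s%02d", i); labels[r] <- "m1"
  }
  for (i in seq_len(n)) {
    r <- r + 1L; X[r, ] <- drawSample(poolM2)
    rownames(X)[r] <- sprintf("m2_s%02d", i); labels[r] <- "m2"
  }
  for (i in seq_len(n)) {
    r <- r + 1L
    X[r, ] <- drawSample(poolM3[((i - 1L) * 6L + 1L):(i * 6L)])
    rownames(X)[r] <- sprintf("m3_s%02d", i); labels[r] <- "m3"
  }
  list(profiles = profileTable(X, normalized = TRUE),
       hierarchy = h,
       groups = stats::setNames(factor(labels), rownames(X)))
}

#' Write a simulated dataset to the standard on-disk formats
#'
#' Writes `profiles.tsv` (features as rows), `hierarchy.tsv` and
#' `metadata.tsv` into a directory, so simulated fixtures feed the
#' command-line workflow end to end.
#'
#' @param sim a list as returned by the simulators.
#' @param dir output directory (created if missing).
#' @return character vector of the three file paths, invisibly.
#' @export
writeSyntheticDataset <- function(sim, dir) {
  stopifnot(all(c("profiles", "hierarchy", "groups") %in% names(sim)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("profiles.tsv", "hierarchy.tsv", "metadata.tsv"))
  writeProfileTable(sim$profiles, paths[1L])
  writeHierarchy(sim$hierarchy, paths[2L])
  writeGroupLabels(sim$groups, paths[3L])
  invisible(paths)
}
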