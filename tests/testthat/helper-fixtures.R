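# Shared fixture builders. Everything is generated in code; no binary
# data.

toyHierarchy <- function() {
  functionHierarchy(
    koToL3 = list(K1 = c("P1", "P2"), K2 = "P2"),
    l3ToL2 = list(P1 = "Q1", P2 = "Q1"),
    l2ToL1 = list(Q1 = "R1")
  )
}

writeTempLines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

randomProfiles <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(runif(n * m), n, m,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("K%03d", seq_len(m))))
  profileTable(X)
}

# random hierarchy over given features: each feature -> 1-2 of nl3
# level-3 pathways, tree above
randomHierarchy <- function(features, nl3 = 6, seed = 1) {
  set.seed(seed)
  l3 <- sprintf("P%02d", seq_len(nl3))
  ko2l3 <- lapply(seq_along(features),
                  function(i) sample(l3, sample(1:2, 1)))
  names(ko2l3) <- features
  l2 <- c("Q1", "Q2")
  l3ToL2 <- setNames(as.list(rep(l2, length.out = nl3)), l3)
  functionHierarchy(ko2l3, l3ToL2, list(Q1 = "R1", Q2 = "R2"))
}

betweenMean <- function(M, g, a, b) mean(M[g == a, g == b])

withinVals <- function(M, g, a) {
  sub <- M[g == a, g == a]
  sub[upper.tri(sub)]
}

rotationMatrix3 <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# independent brute-force classical MDS: explicit centering matrix and a
# dense eigendecomposition, kept free of the package's pcoa() code path
bruteForceMds <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  sweep(e$vectors[, seq_len(k), drop = FALSE], 2,
        sqrt(pmax(e$values[seq_len(k)], 0)), `*`)
}
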