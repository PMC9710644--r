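test_that("the two-point embedding is forced by centering and scaling", {
  v <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- pcoa(distanceMatrix(v), k = 1)
  expect_equal(unname(res@coordinates[, 1]), c(0.5, -0.5))
  expect_equal(res@eigenvalues, 0.5)
  expect_equal(res@explained, 1)
  expect_equal(res@nNegative, 0L)
})

test_that("planar Euclidean distances round-trip through the embedding", {
  set.seed(17)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:5), paste0("s", 1:5))
  res <- pcoa(distanceMatrix(D), k = 2)
  expect_equal(as.matrix(dist(res@coordinates)), D,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("requesting more axes than positive eigenvalues warns and reduces", {
  set.seed(18)
  pts <- matrix(rnorm(12), 6, 2)                  # rank-2 configuration
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_warning(res <- pcoa(distanceMatrix(D), k = 5), "reduced")
  expect_equal(ncol(res@coordinates), 2)
  expect_equal(sum(res@explained), 1, tolerance = 1e-9)
})

test_that("degenerate and invalid inputs are handled", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(res <- pcoa(distanceMatrix(z), k = 2), "0")
  expect_equal(ncol(res@coordinates), 0)
  expect_equal(res@nNegative, 0L)
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(pcoa(distanceMatrix(d), k = 2), "smaller than")
  expect_error(pcoa(distanceMatrix(d), k = 0), "positive")
})

test_that("eigenvalues and |coordinates| match an independent dense solver", {
  # Euclidean configurations and a hierarchical-dissimilarity matrix
  mats <- list()
  set.seed(23)
  pts <- matrix(rnorm(120), 40, 3)
  m1 <- as.matrix(dist(pts))
  dimnames(m1) <- list(paste0("s", 1:40), paste0("s", 1:40))
  mats$euclid <- m1
  sim <- simulateConvergentPathways(syntheticDesign(seed = 23))
  mats$hms <- as.matrix(pairwiseDistances(sim$profiles, "hms", sim$hierarchy))

  for (D in mats) {
    k <- 3
    res <- pcoa(distanceMatrix(D), k = k)
    ref <- stats::cmdscale(D, k = k, eig = TRUE)
    expect_equal(res@eigenvalues, ref$eig[seq_len(k)], tolerance = 1e-6)
    expect_equal(abs(res@coordinates), abs(ref$points),
                 ignore_attr = TRUE, tolerance = 1e-6)
    # axis columns: mutually orthogonal, zero mean
    expect_equal(unname(colMeans(res@coordinates)), rep(0, k),
                 tolerance = 1e-9)
    G <- crossprod(res@coordinates)
    offdiag <- abs(G[upper.tri(G)]) / max(diag(G))
    expect_true(all(offdiag < 1e-8))
    expect_lte(sum(res@explained), 1 + 1e-12)
  }
})

test_that("axis signs follow the largest-loading convention, reproducibly", {
  sim <- simulateConvergentPathways(syntheticDesign(seed = 5))
  d <- pairwiseDistances(sim$profiles, "hms", sim$hierarchy)
  r1 <- pcoa(d, k = 3); r2 <- pcoa(d, k = 3)
  expect_identical(r1@coordinates, r2@coordinates)
  for (j in 1:3) {
    col <- r1@coordinates[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("PCoA results round-trip through the coordinates file format", {
  sim <- simulateConvergentPathways(syntheticDesign(seed = 9))
  res <- pcoa(pairwiseDistances(sim$profiles, "hms", sim$hierarchy), k = 3)
  path <- tempfile(fileext = ".tsv")
  writePcoa(res, path)
  back <- readPcoa(path)
  expect_equal(back, res@coordinates, tolerance = 1e-10)
})

test_that("Procrustes correlation is invariant to rotation plus scaling", {
  set.seed(41)
  A <- matrix(rnorm(30 * 3), 30, 3)
  B <- 3.7 * A %*% rotationMatrix3(c(0.4, -1.1, 2.2)) +
    matrix(rep(c(5, -2, 1), each = 30), 30, 3)
  res <- procrustesTest(A, B, permutations = 199, seed = 1)
  expect_equal(res$correlation, 1, tolerance = 1e-10)
  expect_lte(res$pValue, 1 / 200 + 1e-12)
  self <- procrustesTest(A, A, permutations = 99, seed = 2)
  expect_equal(self$correlation, 1, tolerance = 1e-12)
  expect_lte(self$pValue, 1 / 100 + 1e-12)
})

test_that("Procrustes statistic agrees with vegan's symmetric protest", {
  set.seed(43)
  A <- matrix(rnorm(20 * 3), 20, 3)
  B <- A + 0.3 * matrix(rnorm(20 * 3), 20, 3)
  ours <- procrustesTest(A, B, permutations = 99, seed = 1)$correlation
  ref <- vegan::protest(A, B, permutations = 29)$t0
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("Procrustes null: unrelated configurations give non-small p", {
  set.seed(47)
  ps <- replicate(10, {
    A <- matrix(rnorm(30 * 3), 30, 3)
    B <- matrix(rnorm(30 * 3), 30, 3)
    procrustesTest(A, B, permutations = 99,
                   seed = sample.int(1e6, 1))$pValue
  })
  expect_gt(mean(ps), 0.15)   # uniform-ish under the null
  expect_error(procrustesTest(matrix(0, 3, 2), matrix(0, 4, 2)), "rows")
})
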