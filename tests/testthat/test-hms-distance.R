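test_that("brayCurtis matches its closed forms and degenerate cases", {
  expect_equal(brayCurtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
  expect_equal(brayCurtis(c(0.5, 0.5), c(0.25, 0.75)), 0.25)
  expect_equal(brayCurtis(c(0, 0), c(0, 0)), 0)     # both empty -> identical
  expect_error(brayCurtis(c(1, 0), c(1, 0, 0)), "length")
  expect_error(brayCurtis(c(-1, 2), c(1, 0)), "negative")
  expect_error(brayCurtis(c(a = 1, b = 0), c(b = 1, a = 0)), "aligned")
})

test_that("brayCurtis agrees with vegan on random abundance matrices", {
  for (seed in 1:5) {
    X <- abundances(normalizeProfiles(randomProfiles(6, 20, seed)))
    ours <- sapply(2:6, function(j) brayCurtis(X[1, ], X[j, ]))
    ref <- as.matrix(vegan::vegdist(X, method = "bray"))[1, 2:6]
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
  }
})

test_that("collapsing adds each gene family to every annotated pathway", {
  h <- toyHierarchy()
  l3 <- collapseProfile(c(K1 = 0.6, K2 = 0.4), h, level = 3)
  expect_equal(l3, c(P1 = 0.6, P2 = 1.0))
  # single-parent aggregation conserves totals level by level
  l2 <- collapseProfile(c(K1 = 0.6, K2 = 0.4), h, level = 2)
  expect_equal(unname(l2), sum(l3))
  l1 <- collapseProfile(c(K1 = 0.6, K2 = 0.4), h, level = 1)
  expect_equal(unname(l1), unname(l2))
})

test_that("gene families absent from the hierarchy collapse to nothing", {
  h <- toyHierarchy()
  expect_warning(v <- collapseProfile(c(KX = 0.5, KY = 0.5), h, 3),
                 "absent from the hierarchy")
  expect_equal(v, c(P1 = 0, P2 = 0))
  # covered + uncovered mixture: only the covered part lands on pathways
  expect_warning(v2 <- collapseProfile(c(K1 = 0.5, KX = 0.5), h, 3), "KX")
  expect_equal(v2, c(P1 = 0.5, P2 = 0.5))
})

test_that("hmsDistance reproduces the weighted-mean closed forms", {
  h <- functionHierarchy(list(K1 = "P1", K2 = "P1"),
                         list(P1 = "Q1"), list(Q1 = "R1"))
  a <- c(K1 = 1, K2 = 0); b <- c(K1 = 0, K2 = 1)
  expect_equal(hmsDistance(a, a, h), 0)
  # disjoint gene families, identical collapsed pathways: 4*1/10
  expect_equal(hmsDistance(a, b, h), 0.4)
  # disjoint at every level
  h2 <- functionHierarchy(list(K1 = "P1", K2 = "P2"),
                          list(P1 = "Q1", P2 = "Q2"),
                          list(Q1 = "R1", Q2 = "R2"))
  expect_equal(hmsDistance(a, b, h2), 1)
})

test_that("zero pathway-level weights reduce HMS to plain Bray-Curtis", {
  feats <- sprintf("K%03d", 1:12)
  h <- randomHierarchy(feats, seed = 4)
  X <- abundances(normalizeProfiles(randomProfiles(4, 12, seed = 4)))
  w <- hmsWeights(w0 = 4, w1 = 0, w2 = 0, w3 = 0)
  for (j in 2:4)
    expect_equal(hmsDistance(X[1, ], X[j, ], h, w),
                 brayCurtis(X[1, ], X[j, ]))
})

test_that("HMS is a weighted mean: bounded by the per-level extremes", {
  feats <- sprintf("K%03d", 1:15)
  for (seed in 1:5) {
    h <- randomHierarchy(feats, seed = seed)
    X <- abundances(normalizeProfiles(randomProfiles(5, 15, seed = seed + 50)))
    for (i in 1:4) for (j in (i + 1):5) {
      lv <- c(
        brayCurtis(X[i, ], X[j, ]),
        brayCurtis(collapseProfile(X[i, ], h, 3), collapseProfile(X[j, ], h, 3)),
        brayCurtis(collapseProfile(X[i, ], h, 2), collapseProfile(X[j, ], h, 2)),
        brayCurtis(collapseProfile(X[i, ], h, 1), collapseProfile(X[j, ], h, 1)))
      d <- hmsDistance(X[i, ], X[j, ], h)
      expect_gte(d, min(lv) - 1e-12)
      expect_lte(d, max(lv) + 1e-12)
    }
  }
})

test_that("identically permuting the feature order changes nothing", {
  feats <- sprintf("K%03d", 1:12)
  h <- randomHierarchy(feats, seed = 7)
  X <- abundances(normalizeProfiles(randomProfiles(2, 12, seed = 7)))
  set.seed(99)
  for (rep in 1:5) {
    perm <- sample(ncol(X))
    expect_equal(hmsDistance(X[1, perm], X[2, perm], h),
                 hmsDistance(X[1, ], X[2, ], h))
  }
})

test_that("pairwiseDistances equals the per-pair brute force, any workers", {
  p <- normalizeProfiles(randomProfiles(8, 15, seed = 11))
  h <- randomHierarchy(featureNames(p), seed = 11)
  d1 <- pairwiseDistances(p, "hms", h, workers = 1)
  d4 <- pairwiseDistances(p, "hms", h, workers = 4)
  expect_identical(as.matrix(d1), as.matrix(d4))
  X <- abundances(p)
  M <- as.matrix(d1)
  for (i in 1:7) for (j in (i + 1):8)
    expect_identical(M[i, j], hmsDistance(X[i, ], X[j, ], h))
})

test_that("pairwise matrices satisfy the testable metric axioms", {
  for (metric in c("hms", "bray_curtis", "cosine", "euclidean", "jsd")) {
    p <- normalizeProfiles(randomProfiles(6, 10, seed = 21))
    h <- randomHierarchy(featureNames(p), seed = 21)
    M <- as.matrix(pairwiseDistances(p, metric, h))
    expect_identical(M, t(M))
    expect_equal(unname(diag(M)), rep(0, 6))
    expect_true(all(M >= 0))
    if (metric %in% c("hms", "bray_curtis", "cosine"))
      expect_true(all(M <= 1 + 1e-12))
  }
})

test_that("a one-sample table yields the 1x1 zero matrix", {
  p <- normalizeProfiles(randomProfiles(1, 5, seed = 2))
  d <- pairwiseDistances(p, "bray_curtis")
  expect_equal(as.matrix(d),
               matrix(0, 1, 1, dimnames = list("S01", "S01")))
})

test_that("uncovered gene families trigger one summary warning", {
  p <- normalizeProfiles(randomProfiles(3, 4, seed = 5))
  h <- functionHierarchy(list(K001 = "P1"), list(P1 = "Q1"), list(Q1 = "R1"))
  expect_warning(pairwiseDistances(p, "hms", h),
                 "3 gene families absent")
  expect_error(pairwiseDistances(p, "hms", h = NULL), "requires")
})
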