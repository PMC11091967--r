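test_that("tanimoto matches set-arithmetic identities and hand counts", {
  a <- c(0, 1, 1, 1, 0, 0)
  b <- c(0, 0, 1, 1, 1, 0)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(a, b), 0.5)            # bits {2,3,4} vs {3,4,5}: 2/4
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(rep(0, 6), rep(0, 6)), "all-zero")
  expect_error(tanimoto(a, c(1, 0)), "length")
})

test_that("tanimoto agrees exactly with a brute-force oracle on random pairs", {
  withr::with_seed(11, {
    for (i in 1:200) {
      a <- rbinom(64, 1, 0.3)
      b <- rbinom(64, 1, 0.3)
      if (sum(a | b) == 0) a[1] <- 1
      expect_identical(tanimoto(a, b), bruteTanimoto(a, b))
    }
  })
})

test_that("PCA embedding captures variance structure and reconstructs data", {
  # variation along a single direction: first component explains everything
  base <- rep(c(0, 1), each = 10)
  M <- rbind(matrix(rep(c(rep(0, 20)), 10), 10, byrow = TRUE),
             matrix(rep(base, 10), 10, byrow = TRUE))
  emb <- embedFingerprints(M, d = 3)
  expect_equal(emb$explainedVarianceRatio[1], 1.0)

  # full-rank reconstruction reproduces the centered data
  withr::with_seed(5, M2 <- matrix(rbinom(50 * 40, 1, 0.4), 50, 40))
  embF <- embedFingerprints(M2, d = 40)
  centered <- scale(M2, center = TRUE, scale = FALSE)
  recon <- embF$scores %*% t(embF$rotation)
  expect_equal(unname(recon), unname(centered)[, seq_len(ncol(recon))],
               tolerance = 1e-9)

  expect_error(embedFingerprints(matrix(1, 30, 5), d = 2), "constant")
})

test_that("compound correlation matches brute-force Pearson and flags degeneracy", {
  withr::with_seed(6, S <- matrix(rnorm(5 * 10), 5, 10))
  emb <- structure(list(scores = S, explainedVarianceRatio = rep(0.1, 10),
                        d = 10, rotation = diag(10)),
                   class = "FingerprintEmbedding")
  R <- compoundCorrelation(emb, nDims = 10)
  expect_true(isSymmetric(unname(R)))
  expect_equal(unname(diag(R)), rep(1, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    num <- sum((S[i, ] - mean(S[i, ])) * (S[j, ] - mean(S[j, ])))
    den <- sqrt(sum((S[i, ] - mean(S[i, ]))^2) * sum((S[j, ] - mean(S[j, ]))^2))
    expect_equal(R[i, j], num / den, tolerance = 1e-12)
  }
  # identical and negated rows
  S2 <- rbind(S[1, ], S[1, ], -S[1, ])
  emb2 <- structure(list(scores = S2, explainedVarianceRatio = rep(0.1, 10),
                         d = 10, rotation = diag(10)),
                    class = "FingerprintEmbedding")
  R2 <- compoundCorrelation(emb2, nDims = 10)
  expect_equal(R2[1, 2], 1.0)
  expect_equal(R2[1, 3], -1.0)
  # zero-variance compound flagged
  S3 <- rbind(S, rep(2, 10))
  emb3 <- structure(list(scores = S3, explainedVarianceRatio = rep(0.1, 10),
                         d = 10, rotation = diag(10)),
                    class = "FingerprintEmbedding")
  R3 <- compoundCorrelation(emb3, nDims = 10)
  expect_true(all(is.na(R3[6, -6])))
  expect_equal(attr(R3, "flagged"), 6L)
})

test_that("kneedle knee selection finds a sharp elbow and rejects linear curves", {
  k <- 2:12
  inertia <- c(20, 10, 10 - 0.1 * (1:9))        # slope -10 then -0.1: elbow at 3
  expect_equal(as.integer(selectKneedle(k, inertia)), 3L)
  expect_identical(as.integer(selectKneedle(k, inertia)),
                   as.integer(kneedleBrute(k, inertia)))
  # brute-force agreement on random convex decreasing curves
  withr::with_seed(9, {
    for (i in 1:20) {
      drops <- sort(runif(10, 0.1, 5), decreasing = TRUE)
      curve <- 30 - cumsum(c(0, drops))
      expect_identical(as.integer(selectKneedle(2:12, curve)),
                       as.integer(kneedleBrute(2:12, curve)))
    }
  })
  expect_error(selectKneedle(2:12, seq(22, 2, by = -2)), "linear")
  expect_error(selectKneedle(2:4, c(3, 2, 1)), "at least 4")
  expect_error(selectKneedle(2:6, c(5, 4, 4.5, 2, 1)), "nonincreasing")
})

test_that("k-means clustering recovers planted partitions", {
  withr::with_seed(21, {
    blobA <- matrix(rnorm(40, mean = 0, sd = 0.1), 20, 2)
    blobB <- matrix(rnorm(40, mean = 5, sd = 0.1), 20, 2)
  })
  X <- rbind(blobA, blobB)
  rownames(X) <- sprintf("m%02d", 1:40)
  cm <- clusterCompounds(X, k = 2, seed = 1)
  expect_equal(clusterPurity(clusterLabels(cm), rep(1:2, each = 20)), 1.0)
  # representative is the row nearest its centroid
  for (cl in 1:2) {
    idx <- which(clusterLabels(cm) == cl)
    d2 <- rowSums((X[idx, , drop = FALSE] -
                     matrix(cm@centroids[cl, ], length(idx), 2, byrow = TRUE))^2)
    expect_identical(representatives(cm)[cl], names(idx)[which.min(d2)])
  }
  # k = n drives inertia to zero
  cmN <- clusterCompounds(X[1:6, ], k = 6, seed = 1)
  expect_equal(cmN@inertia, 0)
  expect_error(clusterCompounds(X, k = 41), "exceeds")
})

test_that("planted 3-cluster libraries are recovered with high agreement", {
  skip_if_not_installed("mclust")
  agree <- vapply(1:5, function(s) {
    lib <- simulateAssayLibrary(nAssays = 6, compoundsPerAssay = 20,
                                nClustersTrue = 3, seed = s)
    emb <- embedFingerprints(lib$assays, d = 20)
    cm <- clusterCompounds(emb$scores[, 1:10], k = 3, seed = s)
    mclust::adjustedRandIndex(clusterLabels(cm), lib$truth$compoundCluster)
  }, numeric(1))
  expect_true(all(agree >= 0.95))
})

test_that("quadrant score partitions compounds and matches hand arithmetic", {
  fpA <- rep(c(1L, 0L), c(10, 10))
  # all compounds identical to the reference: everything lands in Q2/Q4
  same <- toyAssay(ac50 = seq(0.2, 2, length.out = 21),
                   fps = matrix(rep(fpA, 21), 21, byrow = TRUE))
  qsSame <- quadrantScore(same, minCompounds = 0)
  expect_equal(toleranceScore(qsSame), 0)
  expect_equal(unname(quadrantCounts(qsSame)[c("q1", "q3")]), c(0L, 0L))

  # constructed counts q3=5, q1=2, q2=3, q4=10 -> score 1.0
  fpB <- rep(c(0L, 1L), c(10, 10))          # disjoint from fpA: similarity 0
  fps <- rbind(matrix(rep(fpA, 1 + 10 + 3), 14, byrow = TRUE),  # ref, Q4, Q2
               matrix(rep(fpB, 5 + 2), 7, byrow = TRUE))        # Q3, Q1
  ac <- c(0.001, rep(0.01, 10), rep(5, 3), rep(0.01, 5), rep(5, 2))
  qs <- quadrantScore(toyAssay(ac, fps), minCompounds = 0)
  expect_equal(unname(quadrantCounts(qs)), c(2L, 3L, 5L, 10L))
  expect_equal(toleranceScore(qs), 1.0)
  expect_equal(sum(quadrantCounts(qs)), length(ac) - 1L)
  expect_identical(qs@referenceCid, "c01")

  # flagged-infinite: q3 > 0 with empty denominator
  qsInf <- quadrantScore(toyAssay(c(0.001, rep(0.01, 3), rep(0.02, 4)),
                                  rbind(matrix(rep(fpA, 4), 4, byrow = TRUE),
                                        matrix(rep(fpB, 4), 4, byrow = TRUE))),
                         minCompounds = 0)
  expect_true(qsInf@infinite)
  expect_identical(toleranceScore(qsInf), Inf)

  expect_error(quadrantScore(toyAssay(c(0.01, rep(1, 20)),
                                      rbind(rep(0L, 20),
                                            matrix(rep(fpA[1:20], 20), 20, byrow = TRUE))),
                             minCompounds = 0), "all-zero")
  expect_error(quadrantScore(same, minCompounds = 30), "inclusion")
})

test_that("quadrant counts partition n-1 and the dissimilar margin is cutoff-invariant", {
  lib <- simulateAssayLibrary(tolerantAssay = 4, seed = 3)
  a <- lib$assays[[4]]
  dissimilar <- NULL
  for (pc in c(0.02, 0.05, 0.1, 0.5, 2)) {
    qs <- quadrantScore(a, potencyCutoff = pc)
    expect_equal(sum(quadrantCounts(qs)), length(a) - 1L)
    # q1 + q3 = number of dissimilar compounds: unchanged by the potency cut
    dis <- qs@q1 + qs@q3
    if (is.null(dissimilar)) dissimilar <- dis
    expect_identical(dis, dissimilar)
  }
})

test_that("assay ranking orders by score with infinite flags first", {
  fpA <- rep(c(1L, 0L), c(10, 10)); fpB <- rep(c(0L, 1L), c(10, 10))
  mk <- function(aid, ac, fps) quadrantScore(toyAssay(ac, fps, aid), minCompounds = 0)
  sZero <- mk("Z", seq(0.2, 2, length.out = 5), matrix(rep(fpA, 5), 5, byrow = TRUE))
  sHalf <- mk("H", c(0.001, 0.01, rep(5, 2)),
              rbind(fpA, fpB, fpB, fpB))
  sInf <- mk("I", c(0.001, rep(0.01, 3)),
             rbind(matrix(rep(fpA, 2), 2, byrow = TRUE),
                   matrix(rep(fpB, 2), 2, byrow = TRUE)))
  r <- rankAssays(list(sZero, sHalf, sInf))
  expect_identical(r$aid, c("I", "H", "Z"))
  expect_identical(r$rank, 1:3)
  single <- rankAssays(sZero)
  expect_identical(single$aid, "Z")
})
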