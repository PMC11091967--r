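test_that("library generation is seed-reproducible and respects zero noise", {
  lib1 <- simulateAssayLibrary(nAssays = 3, compoundsPerAssay = 20,
                               nClustersTrue = 2, seed = 4)
  lib2 <- simulateAssayLibrary(nAssays = 3, compoundsPerAssay = 20,
                               nClustersTrue = 2, seed = 4)
  expect_identical(lib1, lib2)
  expect_true(all(fingerprints(lib1$assays[[1]]) %in% c(0L, 1L)))

  # zero flip noise: every compound equals its cluster prototype exactly
  lib0 <- simulateAssayLibrary(nAssays = 4, compoundsPerAssay = 20,
                               nClustersTrue = 2, bitflipNoise = 0, seed = 2)
  for (i in seq_along(lib0$assays)) {
    proto <- lib0$truth$prototypes[lib0$truth$assayCluster[i], ]
    fp <- fingerprints(lib0$assays[[i]])
    expect_true(all(apply(fp, 1L, identical, as.integer(proto))))
  }
})

test_that("zero-noise planted partitions are exactly separable by k-means", {
  lib <- simulateAssayLibrary(nAssays = 6, compoundsPerAssay = 20,
                              nClustersTrue = 3, bitflipNoise = 0, seed = 1)
  M <- do.call(rbind, lapply(lib$assays, fingerprints))
  km <- clusterCompounds(M, k = 3, seed = 1)
  expect_equal(clusterPurity(clusterLabels(km), lib$truth$compoundCluster), 1.0)
})

test_that("only the designated assay carries potent-and-dissimilar compounds", {
  lib <- simulateAssayLibrary(tolerantAssay = 2, seed = 1)
  # oracle: direct count over the generated records, no quadrant code
  directCount <- vapply(lib$assays, function(a) {
    fp <- fingerprints(a); ac <- ac50(a)
    ref <- which.min(ac)
    sum(vapply(seq_along(ac), function(i) {
      i != ref && ac[i] < 0.1 && bruteTanimoto(fp[i, ], fp[ref, ]) < 0.8
    }, logical(1)))
  }, numeric(1))
  expect_true(directCount[2] >= 1)
  expect_true(all(directCount[-2] == 0))
  scores <- lapply(lib$assays, quadrantScore)
  positive <- vapply(scores, function(s) toleranceScore(s) > 0, logical(1))
  expect_identical(which(positive), 2L)
  expect_error(simulateAssayLibrary(prototypes = matrix(0:1, 2, 10), fpLength = 881),
               "bits")
})

test_that("image pairs carry the planted background and boundary puncta", {
  # zero noise: background pixels are exactly the planted constant (the
  # negative image; membrane puncta of positive cells bleed past the mask)
  pair0 <- simulateImagePair(imageSpec(noiseSd = 0, diffuseBackground = 137, seed = 2))
  expect_equal(as.numeric(estimateBackground(pair0$neg$probe, pair0$neg$mask)), 137)
  expect_identical(sort(unique(as.vector(pair0$pos$mask))), 0:8)
  expect_identical(pair0$pos$truth$puncta, rep(12L, 8))
  expect_identical(pair0$neg$truth$puncta, rep(0L, 8))

  # identical generative law when both members carry no puncta
  pp <- simulateImagePair(imageSpec(punctaPerCell = 0, seed = 5))
  sp <- measureCells(pp$pos$probe, pp$pos$mask,
                     estimateBackground(pp$pos$probe, pp$pos$mask))$skewness
  sn <- measureCells(pp$neg$probe, pp$neg$mask,
                     estimateBackground(pp$neg$probe, pp$neg$mask))$skewness
  expect_lt(abs(median(sp) - median(sn)), 0.2)

  # default pair: positive cells more skewed for >= 90% of cells, checked by
  # direct moment computation on the generated pixels
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    pr <- simulateImagePair(imageSpec(seed = s))
    for (cell in 1:8) {
      skP <- momentSkewness(pr$pos$probe[pr$pos$mask == cell])
      skN <- momentSkewness(pr$neg$probe[pr$neg$mask == cell])
      hits <- hits + (skP > skN); total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)

  expect_error(simulateImagePair(imageSpec(nCells = 60, cellRadius = 40)),
               "non-overlapping")
  expect_error(simulateImagePair(imageSpec(width = 256), imageSpec(width = 128)),
               "geometry")
})

test_that("photophysics generator obeys Beer-Lambert and decays exponentially", {
  ph <- simulatePhotophysics(epsTrue = 14175, phiTrue = 0.288, tauTrue = 2.43)
  expect_equal(ph$absorbance$absorbance,
               14175 * ph$absorbance$concentration, tolerance = 1e-12)
  # emission slopes encode the quantum-yield ratio
  expect_equal(ph$truth$slopeSample / ph$truth$slopeReference, 0.288 / 0.68,
               tolerance = 1e-12)
  # identity case: same slopes, same solvent -> reference yield back
  expect_equal(relativeQuantumYield(5, 5), 0.68)
  lam <- ph$decay$counts - 10
  expect_equal(lam, 1e4 * exp(-ph$decay$time / 2.43), tolerance = 1e-9)
})

test_that("dose-response generator hits the midpoint identity and exact fits", {
  dr0 <- simulateDoseResponse(trueEc50 = 0.5, noiseCv = 0, concentrations = c(0.1, 0.25, 0.5, 1, 2))
  atEc50 <- dr0$response[dr0$concentration == 0.5]
  expect_equal(unique(round(atEc50, 12)), 0.5)      # (top+bottom)/2 with 1/0
  fit <- fitHill(dr0$concentration, dr0$response)
  expect_equal(ec50(fit), 0.5, tolerance = 1e-6)
  expect_error(simulateDoseResponse(0.5, concentrations = c(2, 1)), "sorted")
})
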