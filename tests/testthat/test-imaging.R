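test_that("triangle threshold lands between separated modes", {
  counts <- numeric(210)
  counts[10] <- 100; counts[200] <- 50
  thr <- triangleThreshold(counts)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_warning(thrFlat <- triangleThreshold(rep(3, 100)), "flat")
  expect_equal(thrFlat, (1 + 100) / 2)
  expect_error(triangleThreshold(c(0, 5, 0, 0)), "single-bin")
  expect_error(triangleThreshold(numeric(0)), "empty")

  # bimodal Gaussian mixture: threshold falls between the modes, at the foot
  # of the dominant peak (the triangle method's characteristic placement,
  # cross-checked against scikit-image's threshold_triangle on the same law)
  withr::with_seed(31, {
    for (i in 1:20) {
      x <- c(rnorm(7000, 50, 5), rnorm(3000, 180, 10))
      h <- hist(x, breaks = seq(min(x), max(x), length.out = 257), plot = FALSE)
      thr <- triangleThreshold(h$counts, h$mids)
      expect_gt(thr, 60); expect_lt(thr, 165)
    }
  })
})

test_that("background estimation recovers the planted constant", {
  # uniform image: mean of non-cell pixels regardless of threshold
  mask <- matrix(0L, 32, 32); mask[10:20, 10:20] <- 1L
  expect_equal(as.numeric(estimateBackground(matrix(42, 32, 32), mask)), 42)
  # noisy generator images: within 2% of the planted background
  errs <- vapply(1:20, function(s) {
    img <- simulateImagePair(imageSpec(seed = s))$pos
    abs(as.numeric(estimateBackground(img$probe, img$mask)) - 200) / 200
  }, numeric(1))
  expect_true(all(errs < 0.02))
  expect_error(estimateBackground(matrix(5, 4, 4), matrix(1L, 4, 4)), "non-cell")
})

test_that("per-cell skewness matches the direct moment formula", {
  # hand example {0, 0, 3}: m = 1, m2 = 2, m3 = 2 -> 2/2^1.5 = 1/sqrt(2)
  mask <- matrix(0L, 10, 10); mask[1, 1:3] <- 1L
  probe <- matrix(1, 10, 10); probe[1, 1:3] <- c(0, 0, 3)
  m <- measureCells(probe, mask, background = 1, minPixels = 3)
  expect_equal(m$skewness, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$skewness, momentSkewness(c(0, 0, 3)), tolerance = 1e-12)
  expect_equal(m$mean_raw, 1)

  # agreement with the moment oracle and e1071 on random samples
  skip_if_not_installed("e1071")
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- rlnorm(200, sdlog = runif(1, 0.2, 1))
      mask <- matrix(1L, 20, 10); probe <- matrix(x, 20, 10)
      sk <- measureCells(probe, mask, background = 1)$skewness
      expect_equal(sk, momentSkewness(x), tolerance = 1e-12)
      expect_equal(sk, e1071::skewness(x, type = 1), tolerance = 1e-12)
    }
  })

  # constant cell: flagged undefined; symmetric pixels: near-zero skewness
  maskC <- matrix(1L, 8, 8)
  expect_true(is.na(measureCells(matrix(7, 8, 8), maskC, 1, minPixels = 4)$skewness))
  withr::with_seed(3, g <- rnorm(1e4))
  expect_lt(abs(measureCells(matrix(g, 100, 100), matrix(1L, 100, 100), 1)$skewness), 0.1)
})

test_that("normalized means are scale-equivariant and small cells are dropped", {
  img <- simulateImagePair(imageSpec(seed = 8))$pos
  bg <- estimateBackground(img$probe, img$mask)
  m1 <- measureCells(img$probe, img$mask, bg)
  m2 <- measureCells(img$probe * 3, img$mask, as.numeric(bg) * 3)
  expect_equal(m1$mean_normalized, m2$mean_normalized, tolerance = 1e-12)
  expect_equal(m1$skewness, m2$skewness, tolerance = 1e-9)
  # raise the pixel floor beyond the cell size: everything is dropped
  expect_message(mBig <- measureCells(img$probe, img$mask, bg, minPixels = 1e5),
                 "dropped")
  expect_identical(nrow(mBig), 0L)
})

test_that("group comparison behaves at the null and under large shifts", {
  withr::with_seed(17, base <- rnorm(20, 1, 0.1))
  same <- compareGroups(base, base)
  expect_equal(same$effect, 1)
  expect_gt(same$p_raw, 0.9)
  shifted <- compareGroups(base + 100, base, nComparisons = 3)
  expect_lt(shifted$p_adjusted, 0.001)
  expect_equal(shifted$p_adjusted, min(1, shifted$p_raw * 3))
  expect_error(compareGroups(rep(2, 5), rep(2, 5)), "tied")
  expect_error(compareGroups(1:2, 1:5), "at least 3")
})

test_that("SNR timecourse reports epoch contrast arithmetic", {
  cells <- matrix(100, 5, 10)
  bg <- rep(10, 10)
  tc <- snrTimecourse(cells, bg, splitFrame = 5)
  expect_equal(tc$epochRatio, 1.0)
  # background halves while signal falls to 90%: SNR ratio 1.8
  bg2 <- c(rep(10, 5), rep(5, 5))
  cells2 <- cbind(matrix(100, 5, 5), matrix(90, 5, 5))
  expect_equal(snrTimecourse(cells2, bg2, splitFrame = 5)$epochRatio, 1.8)
  expect_error(snrTimecourse(cells, rep(0, 10)), "positive")
  expect_error(snrTimecourse(cells, rep(1, 9)), "frame counts")
})

test_that("ROI channel correlation recovers planted correlation", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(roiChannelCorrelation(x, 2 * x)$r, 1.0)
  expect_equal(roiChannelCorrelation(x, -x + 30)$r, -1.0)
  expect_error(roiChannelCorrelation(x, rep(2, 5)), "zero variance")
  withr::with_seed(23, {
    rhat <- vapply(1:500, function(i) {
      a <- rnorm(9)
      b <- 0.7 * a + sqrt(1 - 0.49) * rnorm(9)
      roiChannelCorrelation(a, b)$r
    }, numeric(1))
  })
  expect_lt(abs(mean(rhat) - 0.7), 0.1)
})

test_that("fallback segmentation recovers planted cell counts", {
  img <- simulateImagePair(imageSpec(noiseSd = 0, seed = 12))$pos
  lab <- fallbackSegment(img$seg)
  expect_equal(max(lab), 8)
  blank <- fallbackSegment(matrix(0, 64, 64))
  expect_identical(unique(as.vector(blank)), 0L)
})
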