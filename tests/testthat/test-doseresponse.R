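test_that("dF/F0 uses the windowed peak over the baseline", {
  expect_equal(computeDFF0(rep(100, 250)), 0)
  tr <- rep(100, 250); tr[50] <- 250
  expect_equal(computeDFF0(tr), 1.5)
  # peaks outside the first 200 frames are ignored by the window contract
  tr2 <- rep(100, 300); tr2[250] <- 900; tr2[40] <- 150
  expect_equal(computeDFF0(tr2), 0.5)
  expect_error(computeDFF0(rep(100, 150)), "at least 200")
  expect_error(computeDFF0(rep(0, 250)), "nonpositive")
  # multiplicative gain cancels
  expect_equal(computeDFF0(tr * 7.3), computeDFF0(tr), tolerance = 1e-12)
})

test_that("4PL fits recover planted curves in both orientations", {
  dr <- simulateDoseResponse(0.252, hill = 1.3, top = 2, bottom = 0.1, noiseCv = 0)
  fit <- fitHill(dr$concentration, dr$response)
  expect_equal(ec50(fit), 0.252, tolerance = 1e-5)
  expect_equal(hillCoef(fit), 1.3, tolerance = 1e-4)
  expect_true(fit@converged)

  drD <- simulateDoseResponse(15.59, noiseCv = 0, direction = "descending")
  fitD <- fitHill(drD$concentration, drD$response, direction = "descending")
  expect_equal(ec50(fitD), 15.59, tolerance = 1e-4)

  expect_error(fitHill(c(1, 2, 4, 8), rep(3, 4)), "constant")
  expect_error(fitHill(c(1, 2, 4, 4), c(1, 2, 3, 3.2)), "4 distinct")
})

test_that("4PL fitting is scale-equivariant in concentration", {
  dr <- simulateDoseResponse(0.038, noiseCv = 0.05, seed = 9)
  f1 <- fitHill(dr$concentration, dr$response)
  f2 <- fitHill(dr$concentration * 1000, dr$response)
  expect_equal(ec50(f2) / ec50(f1), 1000, tolerance = 1e-4)
  expect_equal(hillCoef(f1), hillCoef(f2), tolerance = 1e-5)
})

test_that("specific-binding ratio curves behave element-wise", {
  conc <- c(1, 3, 10, 30)
  f <- c(100, 200, 400, 800)
  expect_equal(casrSpecificRatio(conc, f, f)$ratio, rep(1, 4))
  expect_equal(casrSpecificRatio(conc, 2 * f, f)$ratio, rep(2, 4))
  expect_error(casrSpecificRatio(conc, f, c(1, 0, 1, 1)), "positive")
  expect_error(casrSpecificRatio(conc, f[1:3], f), "matched")
})

test_that("saturation Kd fits recover planted constants and flag flat curves", {
  sat0 <- simulateSaturationCurve(53.57, noiseCv = 0)
  fit <- fitSaturationKd(sat0$concentration, sat0$ratio)
  expect_equal(fit$kd, 53.57, tolerance = 1e-4)
  expect_false(fit$flagged)
  # no specific binding: ratio flat at 1, Kd unidentifiable
  flat <- fitSaturationKd(c(1, 10, 100, 1000), rep(1, 4))
  expect_true(flat$flagged)
})

test_that("washout tables report EC50 fold shifts against no-wash", {
  mk <- function(ec) {
    dr <- simulateDoseResponse(ec, noiseCv = 0)
    fitHill(dr$concentration, dr$response)
  }
  fits <- list(no_wash = mk(0.037), wash1x = mk(0.38))
  tab <- washoutShift(fits)
  expect_equal(tab$fold_vs_reference[tab$condition == "no_wash"], 1)
  expect_equal(tab$fold_vs_reference[tab$condition == "wash1x"], 0.38 / 0.037,
               tolerance = 1e-3)
  expect_error(washoutShift(list(wash1x = fits$wash1x, wash5x = fits$no_wash),
                            reference = "no_wash"), "missing")
  expect_error(washoutShift(fits["no_wash"]), "at least 2")
  same <- washoutShift(list(no_wash = fits$no_wash, again = fits$no_wash))
  expect_equal(same$fold_vs_reference, c(1, 1))
})
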