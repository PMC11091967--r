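# Photophysical constants from spectrometer exports: extinction coefficient
# (Beer-Lambert regression), relative quantum yield against a reference
# standard, single-exponential fluorescence lifetime, and fluorogenicity
# ratios.

#' Fit an extinction coefficient from an absorbance series
#'
#' Ordinary least squares of absorbance on concentration x path length.
#' Beer-Lambert has no intercept, so the regression is forced through the
#' origin by default; a free intercept can be enabled to diagnose instrument
#' offsets.
#'
#' @param concentrations molar concentrations (>= 3).
#' @param absorbances matched absorbances (dimensionless).
#' @param pathLength cuvette path in cm (default 1).
#' @param intercept logical; FALSE (default) forces the fit through the
#'   origin.
#' @return list: `epsilon` (M^-1 cm^-1), `se`, `r.squared`, `fit` (the lm
#'   object).
#' @export
fitExtinction <- function(concentrations, absorbances, pathLength = 1,
                          intercept = FALSE) {
  if (length(concentrations) != length(absorbances))
    stopf("concentrations and absorbances must be paired")
  if (length(concentrations) < 3L) stopf("need at least 3 concentrations")
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  if (any(absorbances < 0)) stopf("absorbances must be nonnegative")
  x <- concentrations * pathLength
  fit <- if (intercept) stats::lm(absorbances ~ x) else stats::lm(absorbances ~ 0 + x)
  # zero-noise fixtures fit exactly; the perfect-fit warning is expected there
  co <- suppressWarnings(summary(fit))$coefficients
  eps <- co["x", "Estimate"]
  if (eps <= 0) stopf("fitted extinction coefficient is nonpositive (%.3g)", eps)
  list(epsilon = unname(eps), se = unname(co["x", "Std. Error"]),
       r.squared = suppressWarnings(summary(fit))$r.squared, fit = fit)
}

#' Relative fluorescence quantum yield
#'
#' `phi_s = phi_r * (m_s / m_r) * (n_s / n_r)^2`, where `m` are the slopes of
#' the fluorescence-vs-absorbance regression of sample and reference and `n`
#' the refractive indices of their solvents. With identical solvents the
#' index factor is exactly 1.
#'
#' @param slopeSample,slopeReference positive regression slopes.
#' @param nSample,nReference refractive indices (>= 1; default 1.3617, 94%
#'   ethanol, for both).
#' @param phiReference reference quantum yield in (0, 1\] (default 0.68,
#'   Rhodamine B in 94% ethanol).
#' @return quantum yield (numeric(1)); values above 1 are physically suspect
#'   and produce a warning.
#' @export
relativeQuantumYield <- function(slopeSample, slopeReference,
                                 nSample = 1.3617, nReference = 1.3617,
                                 phiReference = 0.68) {
  assertNumber(slopeSample, "slopeSample", lower = 0, closedLower = FALSE)
  assertNumber(slopeReference, "slopeReference", lower = 0, closedLower = FALSE)
  assertNumber(nSample, "nSample", lower = 1)
  assertNumber(nReference, "nReference", lower = 1)
  assertNumber(phiReference, "phiReference", lower = 0, upper = 1, closedLower = FALSE)
  phi <- phiReference * (slopeSample / slopeReference) * (nSample / nReference)^2
  if (phi > 1)
    warnf("quantum yield %.3g exceeds 1: physically suspect input slopes", phi)
  phi
}

# slope of fluorescence on absorbance through the origin, for QY inputs
emissionSlope <- function(absorbance, fluorescence) {
  stats::coef(stats::lm(fluorescence ~ 0 + absorbance))[[1L]]
}

#' Fit a single-exponential fluorescence lifetime
#'
#' `I(t) = I0 * exp(-(t - t_peak)/tau) + baseline`, fitted by nonlinear least
#' squares from the trace peak onward. Start values come from a log-linear
#' fit of the baseline-subtracted tail.
#'
#' @param times increasing time points (e.g. ns).
#' @param intensities nonnegative counts, parallel to `times`.
#' @return list: `tau`, `se`, `i0`, `baseline`, `fit`.
#' @export
fitLifetime <- function(times, intensities) {
  if (length(times) != length(intensities)) stopf("times and intensities must be paired")
  if (is.unsorted(times, strictly = TRUE)) stopf("times must be strictly increasing")
  if (any(intensities < 0)) stopf("intensities must be nonnegative")
  pk <- which.max(intensities)
  t <- times[pk:length(times)] - times[pk]
  y <- intensities[pk:length(intensities)]
  if (length(t) < 10L) stopf("need at least 10 points past the peak")
  if (diff(range(y)) == 0 || stats::cor(t, y) >= 0)
    stopf("trace does not decay after its peak: lifetime undefined")
  base0 <- min(y)
  amp0 <- max(y) - base0
  # crude tau from the log-linear decay of the upper tail
  sel <- y > base0 + 0.05 * amp0
  lf <- stats::lm(log(y[sel] - base0 + 1e-9) ~ t[sel])
  tau0 <- -1 / stats::coef(lf)[[2L]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 5
  fit <- minpack.lm::nlsLM(
    y ~ i0 * exp(-t / tau) + baseline,
    start = list(i0 = amp0, tau = tau0, baseline = base0),
    lower = c(i0 = 0, tau = 1e-12, baseline = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- summary(fit)$coefficients
  list(tau = co["tau", "Estimate"], se = co["tau", "Std. Error"],
       i0 = co["i0", "Estimate"], baseline = co["baseline", "Estimate"],
       fit = fit)
}

#' Fluorogenicity / quenching ratio
#'
#' Fold change of fluorescence upon an additive (e.g. albumin), with the
#' corresponding percent change: `(ratio - 1) * 100` (negative = quenching).
#'
#' @param fWithAdditive fluorescence with the additive.
#' @param fBaseline baseline fluorescence (> 0).
#' @return list: `ratio`, `percentIncrease`.
#' @export
fluorogenicityRatio <- function(fWithAdditive, fBaseline) {
  assertNumber(fWithAdditive, "fWithAdditive", lower = 0)
  assertNumber(fBaseline, "fBaseline", lower = 0, closedLower = FALSE)
  ratio <- fWithAdditive / fBaseline
  list(ratio = ratio, percentIncrease = (ratio - 1) * 100)
}

#' Tabulate a pH profile
#'
#' Pure tabulation (no fit): sorts by pH, preserving the paired intensities.
#'
#' @param pH,intensity paired vectors.
#' @return data.frame sorted by increasing pH.
#' @export
phProfile <- function(pH, intensity) {
  if (length(pH) != length(intensity)) stopf("pH and intensity must be paired")
  ord <- order(pH)
  data.frame(pH = pH[ord], intensity = intensity[ord])
}
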