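# Concentration-response analysis: dF/F0 extraction from calcium
# transients, four-parameter logistic (Hill) fitting for EC50/IC50,
# receptor-specific fluorescence ratios, one-site saturation Kd, and
# washout EC50 tabulation.

# 4PL mean response; hill > 0, orientation via `direction`
hillResponse <- function(conc, ec50, hill, top, bottom,
                         direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  frac <- if (direction == "ascending") 1 / (1 + (ec50 / conc)^hill)
          else 1 / (1 + (conc / ec50)^hill)
  bottom + (top - bottom) * frac
}

#' Peak dF/F0 of a calcium transient
#'
#' `(max over the first `peakWindow` frames - F0) / F0`, with F0 the mean of
#' the first `baselineWindow` frames (the pre-addition baseline).
#'
#' @param frames fluorescence time series (>= `peakWindow` frames).
#' @param baselineWindow frames averaged for F0 (default 10).
#' @param peakWindow frames searched for the peak (default 200).
#' @return dimensionless peak response.
#' @export
computeDFF0 <- function(frames, baselineWindow = 10L, peakWindow = 200L) {
  baselineWindow <- assertCount(baselineWindow, "baselineWindow")
  peakWindow <- assertCount(peakWindow, "peakWindow")
  if (length(frames) < peakWindow)
    stopf("transient has %d frames, need at least %d", length(frames), peakWindow)
  f0 <- mean(frames[seq_len(baselineWindow)])
  if (f0 <= 0) stopf("baseline fluorescence F0 is nonpositive (%.3g)", f0)
  (max(frames[seq_len(peakWindow)]) - f0) / f0
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' 4PL on log10 concentration by nonlinear least squares with multi-start
#' initialization (5 EC50 starts spanning the tested range); the Hill
#' coefficient is bounded to \[0.2, 10\]. The half-maximal concentration is
#' the curve's inflection point (EC50 ascending, IC50 descending).
#'
#' @param concentrations positive concentrations (>= 4 distinct values).
#' @param responses matched responses (replicates as repeated
#'   concentrations).
#' @param direction `"ascending"` (response grows with concentration) or
#'   `"descending"`.
#' @param nStarts number of EC50 multi-starts (default 5).
#' @return a [HillFit-class]; `converged` is FALSE when no start converged
#'   or the data are flat/non-monotone beyond noise.
#' @export
fitHill <- function(concentrations, responses,
                    direction = c("ascending", "descending"), nStarts = 5L) {
  direction <- match.arg(direction)
  if (length(concentrations) != length(responses))
    stopf("concentrations and responses must be paired")
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  if (length(unique(concentrations)) < 4L)
    stopf("need at least 4 distinct concentrations for a 4PL fit")
  if (diff(range(responses)) == 0) stopf("responses are constant: nothing to fit")

  lc <- log10(concentrations)
  y <- responses
  top0 <- max(y); bot0 <- min(y)
  starts <- seq(min(lc), max(lc), length.out = nStarts)
  sign <- if (direction == "ascending") 1 else -1
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(sign * (lec50 - lc) * hill)),
        start = list(bottom = bot0, top = top0, lec50 = s, hill = 1),
        lower = c(bottom = -Inf, top = -Inf, lec50 = min(lc) - 3, hill = 0.2),
        upper = c(bottom = Inf, top = Inf, lec50 = max(lc) + 3, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stopf("no 4PL start converged: data may be non-monotone beyond noise")
  co <- summary(best$fit)$coefficients
  lec50 <- co["lec50", "Estimate"]
  lecSE <- co["lec50", "Std. Error"]
  ec50 <- 10^lec50
  # delta-method SE on the natural scale
  ec50SE <- ec50 * log(10) * lecSE
  topHat <- co["top", "Estimate"]; botHat <- co["bottom", "Estimate"]
  # honest convergence: the fitted span must clearly exceed residual noise
  span <- abs(topHat - botHat)
  sigma <- sqrt(best$rss / max(1L, length(y) - 4L))
  conv <- is.finite(lecSE) && span > 2 * sigma &&
    lec50 > min(lc) - 2 && lec50 < max(lc) + 2
  new("HillFit",
      ec50 = ec50, ec50SE = ec50SE,
      hill = co["hill", "Estimate"], hillSE = co["hill", "Std. Error"],
      top = max(topHat, botHat), bottom = min(topHat, botHat),
      direction = direction, converged = conv,
      residualSS = best$rss, n = length(y))
}

#' Receptor-specific fluorescence ratio curve
#'
#' Element-wise ratio of receptor-positive over receptor-negative
#' fluorescence at matched concentrations; a flat ratio of 1 indicates no
#' specific binding (e.g. under saturating competitor).
#'
#' @param concentrations shared concentration vector.
#' @param fPos,fNeg per-concentration fluorescence of the receptor-positive
#'   and receptor-negative line (`fNeg` > 0 everywhere).
#' @return data.frame (`concentration`, `ratio`) with
#'   `responseKind = "fluorescence_ratio"`.
#' @export
casrSpecificRatio <- function(concentrations, fPos, fNeg) {
  if (length(concentrations) != length(fPos) || length(fPos) != length(fNeg))
    stopf("concentrations, fPos and fNeg must be matched")
  if (any(fNeg <= 0)) stopf("receptor-negative fluorescence must be positive everywhere")
  out <- data.frame(concentration = concentrations, ratio = fPos / fNeg)
  attr(out, "responseKind") <- "fluorescence_ratio"
  out
}

#' Fit a one-site saturation Kd from a fluorescence-ratio curve
#'
#' `ratio(c) = 1 + A * c / (Kd + c)` by nonlinear least squares. When the
#' amplitude is unidentifiable or the Kd standard error exceeds the
#' estimate, the result is flagged as unsaturated.
#'
#' @param concentrations positive concentrations (>= 4).
#' @param ratios matched positive/negative fluorescence ratios.
#' @return list: `kd`, `se`, `amplitude`, `flagged` (TRUE when no saturation
#'   is detectable), `fit`.
#' @export
fitSaturationKd <- function(concentrations, ratios) {
  if (length(concentrations) != length(ratios)) stopf("inputs must be paired")
  if (length(unique(concentrations)) < 4L) stopf("need at least 4 concentrations")
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  a0 <- max(ratios) - 1
  if (a0 <= 0) a0 <- 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratios ~ 1 + A * concentrations / (kd + concentrations),
      start = list(A = a0, kd = stats::median(concentrations)),
      lower = c(A = 0, kd = 1e-15),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), error = function(e) NULL)
  if (is.null(fit))
    # flat / degenerate curves give a singular model: no saturation detectable
    return(list(kd = NA_real_, se = NA_real_, amplitude = NA_real_,
                flagged = TRUE, fit = NULL))
  co <- suppressWarnings(summary(fit))$coefficients
  kd <- co["kd", "Estimate"]; se <- co["kd", "Std. Error"]
  A <- co["A", "Estimate"]
  flagged <- !is.finite(se) || se > kd || A < 1e-6
  list(kd = kd, se = se, amplitude = A, flagged = flagged, fit = fit)
}

#' Tabulate EC50 shifts across wash conditions
#'
#' @param fits named list of [HillFit-class] objects; must contain the
#'   reference condition `reference` (default `"no_wash"`).
#' @param reference name of the no-wash condition.
#' @return data.frame: `condition`, `ec50`, `ec50_se`, `fold_vs_reference`.
#' @export
washoutShift <- function(fits, reference = "no_wash") {
  if (length(fits) < 2L) stopf("need at least 2 wash conditions")
  if (!all(vapply(fits, is, logical(1), "HillFit")))
    stopf("'fits' must be a list of HillFit objects")
  if (!reference %in% names(fits))
    stopf("reference condition '%s' missing from fits", reference)
  ref <- fits[[reference]]@ec50
  data.frame(condition = names(fits),
             ec50 = vapply(fits, function(f) f@ec50, numeric(1)),
             ec50_se = vapply(fits, function(f) f@ec50SE, numeric(1)),
             fold_vs_reference = vapply(fits, function(f) f@ec50 / ref, numeric(1)),
             row.names = NULL)
}
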