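# Receptor-specific labeling quantification in two-channel images:
# triangle-threshold background estimation, per-cell skewness and
# background-normalized mean of probe-channel pixels, rank-based group
# comparisons, quencher SNR timecourses, ROI channel correlation, and a
# classical fallback segmenter for synthetic fixtures.

#' Triangle threshold of an intensity histogram
#'
#' Standard triangle method: draw the line from the histogram peak to the far
#' end of the longer tail, and place the threshold at the bin maximizing the
#' perpendicular distance between histogram and line. Deterministic; a flat
#' histogram is degenerate and returns the midpoint with a warning.
#'
#' @param counts nonnegative bin counts.
#' @param binCenters intensity value of each bin (default the bin index).
#' @return threshold on the `binCenters` scale.
#' @export
triangleThreshold <- function(counts, binCenters = seq_along(counts)) {
  if (!length(counts) || all(counts == 0)) stopf("histogram is empty")
  if (length(counts) != length(binCenters)) stopf("counts and binCenters must be parallel")
  nz <- which(counts > 0)
  if (length(nz) == 1L) stopf("single-bin histogram: threshold undefined")
  if (max(counts) == min(counts)) {
    warnf("flat histogram: triangle threshold degenerate, returning midpoint")
    return((binCenters[1L] + binCenters[length(binCenters)]) / 2)
  }
  p <- which.max(counts)
  leftSpan <- p - nz[1L]
  rightSpan <- nz[length(nz)] - p
  e <- if (rightSpan >= leftSpan) nz[length(nz)] else nz[1L]
  if (e == p) stopf("degenerate histogram: peak at the tail end")
  idx <- if (e > p) p:e else e:p
  # normalized coordinates: bin index over the span, counts over the peak
  x <- (idx - p) / (e - p)
  y <- counts[idx] / counts[p]
  # distance from (x, y) to the line through (0, 1) and (1, y_e)
  ye <- counts[e] / counts[p]
  num <- abs((ye - 1) * x - y + 1)
  d <- num / sqrt((ye - 1)^2 + 1)
  best <- idx[which.max(d)]
  binCenters[best]
}

# 256-bin histogram over the image's min-max range
imageHistogram <- function(img, bins = 256L) {
  r <- range(img)
  breaks <- seq(r[1L], r[2L], length.out = bins + 1L)
  h <- graphics::hist(as.vector(img), breaks = breaks, plot = FALSE)
  list(counts = h$counts, mids = h$mids)
}

#' Estimate the image background of a probe channel
#'
#' Mean intensity of pixels that carry no cellular label (mask 0) and are
#' negative for the probe label, i.e. below the triangle threshold of the
#' probe-channel histogram.
#'
#' @param probe probe-channel matrix.
#' @param mask integer label mask (0 = non-cell), same dimensions.
#' @param bins histogram bins for the triangle threshold (default 256).
#' @param minPixels minimum number of eligible pixels (default 100).
#' @return background intensity (numeric(1)), with the threshold used in
#'   attribute `"threshold"`.
#' @export
estimateBackground <- function(probe, mask, bins = 256L, minPixels = 100L) {
  if (!all(dim(probe) == dim(mask))) stopf("probe and mask dimensions differ")
  if (any(!is.finite(probe))) stopf("probe image contains non-finite pixels")
  outside <- mask == 0L
  if (diff(range(probe)) == 0) {
    if (!any(outside)) stopf("no non-cell pixels available for background estimation")
    return(structure(mean(probe[outside]), threshold = NA_real_))
  }
  h <- imageHistogram(probe, bins)
  thr <- triangleThreshold(h$counts, h$mids)
  eligible <- outside & probe < thr
  if (sum(eligible) < minPixels)
    stopf("only %d background-eligible pixels (< %d): supply a manual background",
          sum(eligible), minPixels)
  structure(mean(probe[eligible]), threshold = thr)
}

# third standardized sample moment, bias-uncorrected (Fisher-Pearson g1)
sampleSkewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Per-cell probe-channel measurements
#'
#' For each labeled cell: pixel count, raw mean, background-normalized mean
#' (`mean_raw / background`), and the skewness of the pixel-intensity
#' distribution (bias-uncorrected Fisher-Pearson g1; high skewness indicates
#' punctate, membrane-receptor-like labeling). Cells below `minPixels` are
#' dropped (count reported in attribute `"dropped"`); zero-variance cells get
#' `NA` skewness.
#'
#' @param probe probe-channel matrix.
#' @param mask integer label mask, same dimensions.
#' @param background positive background intensity (see
#'   [estimateBackground()]).
#' @param minPixels minimum pixels per cell (default 50).
#' @return data.frame: `cell_id`, `n_pixels`, `mean_raw`, `mean_normalized`,
#'   `skewness`.
#' @export
measureCells <- function(probe, mask, background, minPixels = 50L) {
  if (!all(dim(probe) == dim(mask))) stopf("probe and mask dimensions differ")
  assertNumber(background, "background", lower = 0, closedLower = FALSE)
  ids <- sort(unique(mask[mask > 0L]))
  rows <- lapply(ids, function(id) {
    px <- probe[mask == id]
    data.frame(cell_id = id, n_pixels = length(px), mean_raw = mean(px),
               mean_normalized = mean(px) / background,
               skewness = sampleSkewness(px))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cell_id = integer(), n_pixels = integer(),
                                      mean_raw = numeric(),
                                      mean_normalized = numeric(),
                                      skewness = numeric())
  keep <- out$n_pixels >= minPixels
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    message(sprintf("measureCells: dropped %d cell(s) under %d pixels", nDropped, minPixels))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- nDropped
  out
}

#' Compare a per-cell statistic between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with Bonferroni
#' adjustment over `nComparisons` planned comparisons, plus the fold change
#' of group medians.
#'
#' @param a,b numeric vectors, or data.frames from [measureCells()] from
#'   which `field` is taken. `NA` values (flagged-undefined skewness) are
#'   excluded.
#' @param field `"skewness"` or `"mean_normalized"` (used when `a`/`b` are
#'   data.frames).
#' @param nComparisons Bonferroni family size (default 1).
#' @param groups labels for the two groups.
#' @return one-row data.frame: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic` (U), `p_raw`, `p_adjusted`, `effect` (median(a)/median(b)).
#' @export
compareGroups <- function(a, b, field = c("skewness", "mean_normalized"),
                          nComparisons = 1L, groups = c("A", "B")) {
  field <- match.arg(field)
  getv <- function(x) {
    if (is.data.frame(x)) x <- x[[field]]
    x[!is.na(x)]
  }
  va <- getv(a); vb <- getv(b)
  if (length(va) < 3L || length(vb) < 3L)
    stopf("need at least 3 valid values per group (got %d and %d)", length(va), length(vb))
  if (length(unique(c(va, vb))) == 1L)
    stopf("all values are tied across both groups: rank test undefined")
  wt <- stats::wilcox.test(va, vb, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  pAdj <- min(1, wt$p.value * nComparisons)
  data.frame(group_a = groups[1L], group_b = groups[2L],
             n_a = length(va), n_b = length(vb),
             statistic = unname(wt$statistic),
             p_raw = wt$p.value, p_adjusted = pAdj,
             effect = stats::median(va) / stats::median(vb))
}

#' Per-frame signal-to-noise ratios of a labeling timecourse
#'
#' Per frame and cell, SNR = mean cell intensity / frame background; the
#' summary is the across-cell mean per frame. When `splitFrame` is given,
#' the ratio of the post-epoch mean to the pre-epoch mean summarizes a
#' contrast change (e.g. quencher addition).
#'
#' @param cellMeans cells x frames matrix of per-cell mean intensities.
#' @param background per-frame background vector.
#' @param splitFrame last frame of the pre epoch, or `NULL`.
#' @return list: `snr` (cells x frames), `summary` (per-frame mean SNR),
#'   `epochRatio` (post/pre, or `NA`).
#' @export
snrTimecourse <- function(cellMeans, background, splitFrame = NULL) {
  cellMeans <- as.matrix(cellMeans)
  if (ncol(cellMeans) != length(background))
    stopf("frame counts differ: %d columns vs %d background values",
          ncol(cellMeans), length(background))
  if (any(background <= 0)) stopf("background must be positive in every frame")
  snr <- sweep(cellMeans, 2L, background, "/")
  summ <- colMeans(snr)
  ratio <- NA_real_
  if (!is.null(splitFrame)) {
    splitFrame <- assertCount(splitFrame, "splitFrame")
    if (splitFrame >= length(summ)) stopf("splitFrame must leave a post epoch")
    ratio <- mean(summ[(splitFrame + 1L):length(summ)]) / mean(summ[seq_len(splitFrame)])
  }
  list(snr = snr, summary = summ, epochRatio = ratio)
}

#' Correlation of per-ROI mean intensities between two channels
#'
#' @param roiMeansCh1,roiMeansCh2 paired per-ROI mean intensities (n >= 3).
#' @return list: `r` (Pearson), `p` (two-sided), `n`.
#' @export
roiChannelCorrelation <- function(roiMeansCh1, roiMeansCh2) {
  if (length(roiMeansCh1) != length(roiMeansCh2)) stopf("ROI vectors must be paired")
  if (length(roiMeansCh1) < 3L) stopf("need at least 3 ROIs")
  if (stats::var(roiMeansCh1) == 0 || stats::var(roiMeansCh2) == 0)
    stopf("zero variance in one channel: correlation undefined")
  ct <- stats::cor.test(roiMeansCh1, roiMeansCh2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(roiMeansCh1))
}

#' Classical fallback segmentation of a cell channel
#'
#' Triangle threshold on the segmentation channel, connected components,
#' area filter. Intended only for synthetic fixtures; touching cells may be
#' merged into one label (flagged in attribute `"possiblyMerged"` when a
#' component is much larger than the median).
#'
#' @param seg segmentation-channel matrix.
#' @param minArea minimum component area in pixels (default 200).
#' @param bins histogram bins for the threshold (default 256).
#' @return integer label matrix (0 = background).
#' @export
fallbackSegment <- function(seg, minArea = 200L, bins = 256L) {
  if (diff(range(seg)) == 0)
    return(matrix(0L, nrow(seg), ncol(seg)))
  h <- imageHistogram(seg, bins)
  thr <- triangleThreshold(h$counts, h$mids)
  bw <- matrix(as.numeric(seg > thr), nrow(seg), ncol(seg))
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= minArea])
  out <- matrix(0L, nrow(seg), ncol(seg))
  merged <- logical(length(keep))
  if (length(keep)) {
    med <- stats::median(as.numeric(areas[as.character(keep)]))
    for (i in seq_along(keep)) {
      out[lab == keep[i]] <- i
      merged[i] <- areas[as.character(keep[i])] > 1.8 * med
    }
  }
  attr(out, "possiblyMerged") <- which(merged)
  out
}
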