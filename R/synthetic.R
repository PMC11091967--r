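# Seeded generators for every input class the pipeline consumes: clustered
# binary fingerprint libraries with planted potency structure, two-channel
# cell images with membrane-punctate vs diffuse labeling, Beer-Lambert /
# exponential-decay photophysics series, and Hill-shaped response curves.
# All ground truth is returned alongside the data; all randomness flows from
# one explicit seed per call.

#' Simulate a library of fingerprint assays with planted structure
#'
#' Compounds are noisy copies of `nClustersTrue` random prototype bit
#' vectors; each assay draws its compounds from a single scaffold cluster
#' (an assay behaves like one chemotype series) and AC50 values are
#' log-normal around a cluster-specific median sampled log-uniformly in
#' \[0.01, 10\] uM. If `tolerantAssay` is set, that assay additionally
#' receives planted compounds that are both potent (AC50 below
#' `potencyCutoff`) and structurally dissimilar (Tanimoto to the assay's
#' most potent compound forced below 0.4 by swapping in a different
#' prototype); no other assay receives such compounds.
#'
#' The default per-bit flip probability (0.01) keeps same-cluster Tanimoto
#' similarity near 0.9 and cross-cluster similarity near 0.1 on 881-bit
#' prototypes of 15% density, so the planted quadrant structure survives any
#' similarity cutoff in \[0.5, 0.9\].
#'
#' @param nAssays number of assays (default 10).
#' @param compoundsPerAssay compounds per assay (>= 20, the assay-inclusion
#'   rule; default 40).
#' @param fpLength fingerprint length in bits (default 881).
#' @param nClustersTrue number of planted scaffold clusters (default 5).
#' @param tolerantAssay index of the assay that receives planted
#'   potent-and-dissimilar compounds, or `NA` for none (default `NA`).
#' @param potencyCutoff potency boundary in uM used when planting (default
#'   0.1).
#' @param bitflipNoise per-bit flip probability in \[0, 0.5) (default 0.01).
#' @param bitDensity prototype bit density (default 0.15).
#' @param ac50Sdlog log-sd of AC50 around the cluster median (default 0.4).
#' @param plantedFraction fraction of the tolerant assay's compounds that are
#'   planted dissimilar-and-potent (at least 1; default 0.1).
#' @param similarityFloor Tanimoto boundary below which a potent compound in
#'   a non-tolerant assay counts as an accidental tolerant signature; such
#'   compounds have their AC50 redrawn above `potencyCutoff`, keeping the
#'   no-tolerance guarantee exact (default 0.8).
#' @param prototypes optional prototype matrix (`nClustersTrue` x
#'   `fpLength`); generated when `NULL`. A column-count mismatch with
#'   `fpLength` is an error.
#' @param seed RNG seed; generation is bit-identical per seed.
#' @return list: `assays` (list of [FingerprintAssay-class]), `truth`
#'   (prototypes, per-assay cluster, cluster medians, per-compound cluster
#'   labels, planted compound ids, the spec echo).
#' @export
simulateAssayLibrary <- function(nAssays = 10L, compoundsPerAssay = 40L,
                                 fpLength = 881L, nClustersTrue = 5L,
                                 tolerantAssay = NA, potencyCutoff = 0.1,
                                 bitflipNoise = 0.01, bitDensity = 0.15,
                                 ac50Sdlog = 0.4, plantedFraction = 0.1,
                                 similarityFloor = 0.8,
                                 prototypes = NULL, seed = 1L) {
  nAssays <- assertCount(nAssays, "nAssays")
  compoundsPerAssay <- assertCount(compoundsPerAssay, "compoundsPerAssay", min = 20L)
  fpLength <- assertCount(fpLength, "fpLength")
  nClustersTrue <- assertCount(nClustersTrue, "nClustersTrue")
  assertNumber(bitflipNoise, "bitflipNoise", lower = 0, upper = 0.5, closedUpper = FALSE)
  if (!is.null(prototypes) && ncol(prototypes) != fpLength)
    stopf("prototype fingerprints have %d bits but fpLength = %d",
          ncol(prototypes), fpLength)

  withSeed(seed, {
    if (is.null(prototypes)) {
      repeat {
        prototypes <- matrix(
          as.integer(stats::runif(nClustersTrue * fpLength) < bitDensity),
          nrow = nClustersTrue)
        if (all(rowSums(prototypes) > 0) && !anyDuplicated(prototypes)) break
      }
    }
    assayCluster <- rep_len(seq_len(nClustersTrue), nAssays)
    clusterMedian <- 10^stats::runif(nClustersTrue, log10(0.01), log10(10))

    flipBits <- function(proto, n) {
      M <- matrix(rep(proto, each = n), nrow = n)
      if (bitflipNoise > 0) {
        flips <- matrix(stats::runif(n * fpLength) < bitflipNoise, nrow = n)
        M[flips] <- 1L - M[flips]
      }
      storage.mode(M) <- "integer"
      M
    }

    assays <- vector("list", nAssays)
    labels <- list()
    plantedCids <- character()
    for (i in seq_len(nAssays)) {
      cl <- assayCluster[i]
      n <- compoundsPerAssay
      fp <- flipBits(prototypes[cl, ], n)
      a <- stats::rlnorm(n, meanlog = log(clusterMedian[cl]), sdlog = ac50Sdlog)
      lab <- rep(cl, n)
      cid <- sprintf("A%02d-%03d", i, seq_len(n))
      if (!is.na(tolerantAssay) && i == tolerantAssay) {
        nPlant <- max(1L, floor(plantedFraction * n))
        idx <- (n - nPlant + 1L):n
        donor <- if (nClustersTrue > 1L) (cl %% nClustersTrue) + 1L else cl
        # potent but above the series' best compound; dissimilar scaffold
        aPlant <- potencyCutoff * 10^stats::runif(nPlant, log10(0.2), log10(0.9))
        refA <- min(aPlant) * 10^(-stats::runif(1, 0.3, 1))
        fpPlant <- flipBits(prototypes[donor, ], nPlant)
        # force dissimilarity to the assay's most potent compound (< 0.4)
        refFp <- fp[1L, ]
        for (j in seq_len(nPlant)) {
          tries <- 0L
          while (tanimoto(fpPlant[j, ], refFp) >= 0.4 && tries < 50L) {
            fpPlant[j, ] <- flipBits(prototypes[donor, ], 1L)[1L, ]
            tries <- tries + 1L
          }
        }
        fp[idx, ] <- fpPlant
        a[idx] <- aPlant
        a[1L] <- refA            # the series' own best compound stays reference
        lab[idx] <- donor
        plantedCids <- cid[idx]
      } else {
        # guarantee of the planted design: no non-tolerant assay carries a
        # compound that is both potent and dissimilar (flip noise can push a
        # same-cluster fingerprint under the similarity boundary; such
        # structural outliers keep their scaffold's reduced potency)
        ref <- which.min(a)
        sims <- rowTanimoto(fp, fp[ref, ])
        offend <- which(sims < similarityFloor & a < potencyCutoff)
        offend <- setdiff(offend, ref)
        if (length(offend))
          a[offend] <- potencyCutoff * 10^stats::runif(length(offend), 0.02, 0.5)
      }
      labels[[i]] <- stats::setNames(lab, cid)
      assays[[i]] <- FingerprintAssay(aid = sprintf("A%02d", i), cid = cid,
                                      fingerprints = fp, ac50 = a)
    }
    list(
      assays = assays,
      truth = list(prototypes = prototypes, assayCluster = assayCluster,
                   clusterMedian = clusterMedian,
                   compoundCluster = unlist(labels),
                   tolerantAssay = tolerantAssay, plantedCids = plantedCids,
                   spec = list(nAssays = nAssays,
                               compoundsPerAssay = compoundsPerAssay,
                               fpLength = fpLength,
                               nClustersTrue = nClustersTrue,
                               potencyCutoff = potencyCutoff,
                               bitflipNoise = bitflipNoise, seed = seed))
    )
  })
}

#' Specification of one synthetic two-channel microscopy image
#'
#' @param width,height image size in pixels (default 256 x 256).
#' @param nCells number of cells (default 8).
#' @param casrPositive logical; TRUE plants membrane puncta (receptor-positive
#'   labeling), FALSE gives only diffuse in-cell signal.
#' @param punctaPerCell membrane puncta per cell when positive (default 12).
#' @param punctaAmplitude peak punctum intensity above the cell signal
#'   (default 2000; 16-bit-range floats).
#' @param diffuseBackground extracellular background intensity (default 200).
#' @param cellSignal diffuse in-cell probe intensity added inside every cell
#'   (default 300).
#' @param cellTexture log-sd of the multiplicative in-cell intensity texture
#'   (default 0.15); gives diffuse labeling the mild positive skew of real
#'   cells, so skewness fold changes are well defined.
#' @param noiseSd Gaussian pixel noise sd (default 20).
#' @param cellRadius cell radius in pixels (default 24).
#' @param seed RNG seed.
#' @return validated list of class `"ImageSpec"`.
#' @export
imageSpec <- function(width = 256L, height = 256L, nCells = 8L,
                      casrPositive = TRUE, punctaPerCell = 12L,
                      punctaAmplitude = 2000, diffuseBackground = 200,
                      cellSignal = 300, cellTexture = 0.15, noiseSd = 20,
                      cellRadius = 24, seed = 1L) {
  assertCount(width, "width", 16L); assertCount(height, "height", 16L)
  assertCount(nCells, "nCells", 1L)
  assertCount(punctaPerCell, "punctaPerCell", 0L)
  assertNumber(punctaAmplitude, "punctaAmplitude", lower = 0)
  assertNumber(diffuseBackground, "diffuseBackground", lower = 0)
  assertNumber(cellSignal, "cellSignal", lower = 0)
  assertNumber(cellTexture, "cellTexture", lower = 0)
  assertNumber(noiseSd, "noiseSd", lower = 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 nCells = as.integer(nCells), casrPositive = isTRUE(casrPositive),
                 punctaPerCell = as.integer(punctaPerCell),
                 punctaAmplitude = punctaAmplitude,
                 diffuseBackground = diffuseBackground,
                 cellSignal = cellSignal, cellTexture = cellTexture,
                 noiseSd = noiseSd,
                 cellRadius = cellRadius, seed = as.integer(seed)),
            class = "ImageSpec")
}

# one synthetic image: list(seg, probe, mask, truth)
simulateImage <- function(spec) {
  stopifnot(inherits(spec, "ImageSpec"))
  w <- spec$width; h <- spec$height; r <- spec$cellRadius
  withSeed(spec$seed, {
    # non-overlapping cell centers by rejection sampling
    centers <- matrix(NA_real_, 0L, 2L)
    tries <- 0L
    while (nrow(centers) < spec$nCells) {
      cand <- c(stats::runif(1, r + 2, w - r - 2), stats::runif(1, r + 2, h - r - 2))
      ok <- nrow(centers) == 0L ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2L, byrow = TRUE))^2)) > 2 * r + 4)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 5000L)
        stopf("could not place %d non-overlapping cells of radius %g in a %dx%d image",
              spec$nCells, r, w, h)
    }
    xs <- matrix(rep(seq_len(w), h), nrow = w)
    ys <- matrix(rep(seq_len(h), each = w), nrow = w)
    mask <- matrix(0L, w, h)
    for (i in seq_len(spec$nCells)) {
      d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
      mask[d2 <= r^2] <- i
    }
    seg <- 100 + 2900 * (mask > 0)
    probe <- matrix(spec$diffuseBackground, w, h)
    inCell <- mask > 0
    # multiplicative log-normal texture: fluorescence intensity over a cell
    # is heterogeneous (expression, thickness), giving diffuse labeling its
    # mild positive skew
    tex <- if (spec$cellTexture > 0)
      stats::rlnorm(sum(inCell), meanlog = 0, sdlog = spec$cellTexture) else 1
    probe[inCell] <- probe[inCell] + spec$cellSignal * tex
    punctaCount <- integer(spec$nCells)
    if (spec$casrPositive && spec$punctaPerCell > 0L) {
      sigma <- 2
      half <- 6L
      for (i in seq_len(spec$nCells)) {
        ang <- stats::runif(spec$punctaPerCell, 0, 2 * pi)
        px <- centers[i, 1] + r * cos(ang)
        py <- centers[i, 2] + r * sin(ang)
        for (j in seq_len(spec$punctaPerCell)) {
          x0 <- max(1L, floor(px[j]) - half); x1 <- min(w, floor(px[j]) + half)
          y0 <- max(1L, floor(py[j]) - half); y1 <- min(h, floor(py[j]) + half)
          gx <- x0:x1; gy <- y0:y1
          blob <- spec$punctaAmplitude *
            exp(-(outer((gx - px[j])^2, (gy - py[j])^2, "+")) / (2 * sigma^2))
          probe[gx, gy] <- probe[gx, gy] + blob
        }
        punctaCount[i] <- spec$punctaPerCell
      }
    }
    if (spec$noiseSd > 0) {
      seg <- seg + matrix(stats::rnorm(w * h, 0, spec$noiseSd), w, h)
      probe <- probe + matrix(stats::rnorm(w * h, 0, spec$noiseSd), w, h)
      seg[seg < 0] <- 0
      probe[probe < 0] <- 0
    }
    truth <- data.frame(cell_id = seq_len(spec$nCells),
                        cx = centers[, 1], cy = centers[, 2],
                        radius = r, puncta = punctaCount)
    list(seg = seg, probe = probe, mask = mask, truth = truth)
  })
}

#' Simulate a receptor-positive / receptor-negative image pair
#'
#' Both images share the geometry of their specs (which must agree in width
#' and height): a segmentation channel with filled cell bodies, a probe
#' channel with membrane puncta (positive) or only diffuse signal
#' (negative), and the ground-truth integer label mask.
#'
#' @param specPos,specNeg [imageSpec()] objects; `specNeg` defaults to
#'   `specPos` with `casrPositive = FALSE` and a shifted seed.
#' @return list with elements `pos` and `neg` (each `seg`, `probe`, `mask`,
#'   `truth` with per-cell punctum counts).
#' @export
simulateImagePair <- function(specPos = imageSpec(),
                              specNeg = NULL) {
  if (is.null(specNeg)) {
    specNeg <- specPos
    specNeg$casrPositive <- FALSE
    specNeg$seed <- specPos$seed + 10000L
  }
  if (specPos$width != specNeg$width || specPos$height != specNeg$height)
    stopf("image pair must share geometry (%dx%d vs %dx%d)",
          specPos$width, specPos$height, specNeg$width, specNeg$height)
  list(pos = simulateImage(specPos), neg = simulateImage(specNeg))
}

#' Simulate photophysics measurement series with known constants
#'
#' Absorbance follows Beer-Lambert (`A = eps * c * l`, path length 1 cm) over
#' the 150-1350 nM concentration series; the quantum-yield block returns
#' fluorescence-vs-absorbance regression series for sample and reference
#' whose slope ratio equals `phiTrue / phiReference`; the decay trace is a
#' single exponential with optional Poisson counting noise.
#'
#' @param epsTrue extinction coefficient, M^-1 cm^-1.
#' @param phiTrue sample quantum yield in (0, 1\].
#' @param tauTrue fluorescence lifetime (ns).
#' @param seed RNG seed.
#' @param phiReference reference-standard quantum yield (default 0.68,
#'   Rhodamine B in 94% ethanol).
#' @param concentrations molar concentrations for the absorbance series
#'   (default `seq(150e-9, 1350e-9, by = 200e-9)`).
#' @param pathLength cuvette path, cm (default 1).
#' @param absNoise relative (fractional) noise sd on absorbances (default 0).
#' @param decayTimes time grid for the decay, ns (default 0..25 by 0.05).
#' @param decayPeak initial decay amplitude, counts (default 1e4).
#' @param decayBaseline constant offset, counts (default 10).
#' @param decayNoise logical; TRUE adds Poisson counting noise (default
#'   FALSE).
#' @return list: `absorbance` (data.frame concentration/absorbance, with
#'   `pathLength` attribute), `emission` (`sample` and `reference`
#'   data.frames of absorbance vs fluorescence), `decay` (data.frame
#'   time/counts), `truth`.
#' @export
simulatePhotophysics <- function(epsTrue, phiTrue, tauTrue, seed = 1L,
                                 phiReference = 0.68,
                                 concentrations = seq(150e-9, 1350e-9, by = 200e-9),
                                 pathLength = 1, absNoise = 0,
                                 decayTimes = seq(0, 25, by = 0.05),
                                 decayPeak = 1e4, decayBaseline = 10,
                                 decayNoise = FALSE) {
  assertNumber(epsTrue, "epsTrue", lower = 0, closedLower = FALSE)
  assertNumber(phiTrue, "phiTrue", lower = 0, upper = 1, closedLower = FALSE)
  assertNumber(tauTrue, "tauTrue", lower = 0, closedLower = FALSE)
  withSeed(seed, {
    A <- epsTrue * concentrations * pathLength
    if (absNoise > 0) A <- A * (1 + stats::rnorm(length(A), 0, absNoise))
    absorbance <- data.frame(concentration = concentrations, absorbance = A)
    attr(absorbance, "pathLength") <- pathLength

    instrument <- 1e6       # arbitrary detector constant, cancels in the ratio
    aGrid <- seq(0.01, 0.06, length.out = 6L)
    emission <- list(
      sample = data.frame(absorbance = aGrid,
                          fluorescence = instrument * phiTrue * aGrid),
      reference = data.frame(absorbance = aGrid,
                             fluorescence = instrument * phiReference * aGrid)
    )
    lambda <- decayBaseline + decayPeak * exp(-decayTimes / tauTrue)
    counts <- if (decayNoise) stats::rpois(length(lambda), lambda) else lambda
    decay <- data.frame(time = decayTimes, counts = counts)
    list(absorbance = absorbance, emission = emission, decay = decay,
         truth = list(eps = epsTrue, phi = phiTrue, tau = tauTrue,
                      phiReference = phiReference,
                      slopeSample = instrument * phiTrue,
                      slopeReference = instrument * phiReference))
  })
}

#' Simulate a Hill-shaped concentration-response curve
#'
#' `response = bottom + (top - bottom) / (1 + (ec50/c)^hill)` (ascending; the
#' descending form swaps the ratio), multiplied by log-normal noise of
#' coefficient of variation `noiseCv`.
#'
#' @param trueEc50 planted half-maximal concentration (same units as
#'   `concentrations`).
#' @param hill Hill coefficient (> 0; default 1).
#' @param top,bottom asymptotes (defaults 1 and 0).
#' @param concentrations strictly positive, sorted concentrations (default 8
#'   half-log steps around `trueEc50`).
#' @param replicates replicates per concentration (default 3).
#' @param noiseCv multiplicative noise CV (default 0.05).
#' @param direction `"ascending"` (agonist-like) or `"descending"`
#'   (inhibition/viability-like).
#' @param seed RNG seed.
#' @return data.frame (`concentration`, `replicate`, `response`) with
#'   attributes `truth` and `responseKind`.
#' @export
simulateDoseResponse <- function(trueEc50, hill = 1, top = 1, bottom = 0,
                                 concentrations = trueEc50 * 10^seq(-1.75, 1.75, by = 0.5),
                                 replicates = 3L, noiseCv = 0.05,
                                 direction = c("ascending", "descending"),
                                 seed = 1L) {
  direction <- match.arg(direction)
  assertNumber(trueEc50, "trueEc50", lower = 0, closedLower = FALSE)
  if (any(concentrations <= 0) || is.unsorted(concentrations))
    stopf("concentrations must be strictly positive and sorted")
  withSeed(seed, {
    cc <- rep(concentrations, each = replicates)
    mu <- hillResponse(cc, trueEc50, hill, top, bottom, direction)
    if (noiseCv > 0) {
      sdlog <- sqrt(log(1 + noiseCv^2))
      mu <- mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    out <- data.frame(concentration = cc,
                      replicate = rep(seq_len(replicates), length(concentrations)),
                      response = mu)
    attr(out, "truth") <- list(ec50 = trueEc50, hill = hill, top = top,
                               bottom = bottom, direction = direction,
                               noiseCv = noiseCv, seed = seed)
    attr(out, "responseKind") <- "dFF0"
    out
  })
}

#' Simulate a saturation-binding fluorescence-ratio curve
#'
#' One-site model on the receptor-positive over receptor-negative
#' fluorescence ratio: `ratio(c) = 1 + A * c / (Kd + c)`, with multiplicative
#' log-normal noise.
#'
#' @param kd planted dissociation constant (units of `concentrations`).
#' @param amplitude specific-binding amplitude `A` (default 3).
#' @param concentrations positive sorted concentrations (default 8 half-log
#'   steps around `kd`).
#' @param replicates wells per concentration (default 3, mirroring
#'   triplicate binding assays).
#' @param noiseCv multiplicative noise CV per well (default 0.1).
#' @param seed RNG seed.
#' @return data.frame (`concentration`, `replicate`, `ratio`) with attribute
#'   `truth` and `responseKind = "fluorescence_ratio"`.
#' @export
simulateSaturationCurve <- function(kd, amplitude = 3,
                                    concentrations = kd * 10^seq(-1.75, 1.75, by = 0.5),
                                    replicates = 3L, noiseCv = 0.1, seed = 1L) {
  assertNumber(kd, "kd", lower = 0, closedLower = FALSE)
  replicates <- assertCount(replicates, "replicates")
  withSeed(seed, {
    cc <- rep(concentrations, each = replicates)
    mu <- 1 + amplitude * cc / (kd + cc)
    if (noiseCv > 0) {
      sdlog <- sqrt(log(1 + noiseCv^2))
      mu <- mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    out <- data.frame(concentration = cc,
                      replicate = rep(seq_len(replicates), length(concentrations)),
                      ratio = mu)
    attr(out, "truth") <- list(kd = kd, amplitude = amplitude, noiseCv = noiseCv)
    attr(out, "responseKind") <- "fluorescence_ratio"
    out
  })
}
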