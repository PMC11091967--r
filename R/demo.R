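# End-to-end demonstration on synthetic fixtures, and the optional PubChem
# BioAssay fetcher. All science modules are pure/offline; network code lives
# only here.

#' Run every analysis stage on synthetic fixtures
#'
#' Generates a fingerprint library with one planted tolerant assay, a
#' receptor-positive/negative image pair set, zero-noise photophysics series
#' and noisy dose-response curves; runs the scaffold, imaging, photophysics
#' and curve-fitting modules; evaluates the pipeline's recovery properties;
#' and (optionally) writes a JSON report. With a fixed seed the report is
#' byte-identical across runs.
#'
#' @param seed integer seed driving every generator.
#' @param outDir directory for `report.json`, or `NULL` to skip writing.
#' @param tolerantAssay index of the planted tolerant assay (default 3).
#' @param kTrue planted cluster count (default 4).
#' @param nImages image pairs per group (default 3).
#' @return report list (invisibly when `outDir` is given); element `pass`
#'   aggregates all property checks.
#' @export
runDemo <- function(seed = 1L, outDir = NULL, tolerantAssay = 3L, kTrue = 4L,
                    nImages = 3L) {
  seed <- assertCount(seed, "seed", min = 0L)
  checks <- list()

  ## chemical scaffold tolerance
  lib <- simulateAssayLibrary(nAssays = 10L, nClustersTrue = kTrue,
                              tolerantAssay = tolerantAssay, seed = seed)
  chem <- scaffoldAnalysis(lib$assays, kRange = 2:12, seed = seed)
  topAid <- chem$ranking$aid[1L]
  checks$tolerant_assay_top_ranked <- identical(topAid, sprintf("A%02d", tolerantAssay))
  checks$planted_k_recovered <- chem$k == kTrue

  ## imaging specificity
  skewPos <- numeric(); skewNeg <- numeric()
  for (i in seq_len(nImages)) {
    pair <- simulateImagePair(imageSpec(seed = seed + i))
    bgP <- estimateBackground(pair$pos$probe, pair$pos$mask)
    bgN <- estimateBackground(pair$neg$probe, pair$neg$mask)
    skewPos <- c(skewPos, measureCells(pair$pos$probe, pair$pos$mask, bgP)$skewness)
    skewNeg <- c(skewNeg, measureCells(pair$neg$probe, pair$neg$mask, bgN)$skewness)
  }
  cmp <- compareGroups(skewPos, skewNeg, nComparisons = 2L,
                       groups = c("receptor_pos", "receptor_neg"))
  checks$skewness_fold_ge_2 <- cmp$effect >= 2
  checks$skewness_p_adjusted_lt_0.001 <- cmp$p_adjusted < 0.001

  ## photophysics (zero-noise recovery of planted constants)
  ph <- simulatePhotophysics(epsTrue = 14175, phiTrue = 0.288, tauTrue = 2.43,
                             seed = seed)
  eps <- fitExtinction(ph$absorbance$concentration, ph$absorbance$absorbance)
  tau <- fitLifetime(ph$decay$time, ph$decay$counts)
  phi <- relativeQuantumYield(
    emissionSlope(ph$emission$sample$absorbance, ph$emission$sample$fluorescence),
    emissionSlope(ph$emission$reference$absorbance, ph$emission$reference$fluorescence))
  checks$epsilon_recovered <- abs(eps$epsilon - 14175) / 14175 < 1e-6
  checks$tau_recovered <- abs(tau$tau - 2.43) / 2.43 < 1e-4
  checks$phi_recovered <- abs(phi - 0.288) < 1e-9

  ## dose-response
  dr <- simulateDoseResponse(trueEc50 = 0.038, noiseCv = 0.05, seed = seed)
  hf <- fitHill(dr$concentration, dr$response, direction = "ascending")
  sat <- simulateSaturationCurve(kd = 53.57, noiseCv = 0.10, seed = seed)
  kd <- fitSaturationKd(sat$concentration, sat$ratio)
  # one-draw smoke gates: wide enough for single-seed sampling spread, tight
  # enough to catch implementation regressions (the multi-seed recovery
  # statistics live in the test suite)
  checks$ec50_within_tolerance <- abs(log10(hf@ec50 / 0.038)) < 0.15
  checks$kd_within_tolerance <- !kd$flagged && abs(log(kd$kd / 53.57)) < 0.5

  report <- list(
    seed = seed,
    config = list(tolerantAssay = tolerantAssay, kTrue = kTrue,
                  nImages = nImages, potencyCutoff = 0.1,
                  similarityCutoff = 0.8, kRange = c(2L, 12L)),
    scaffold = list(selected_k = chem$k, top_assay = topAid,
                    ranking = chem$ranking[, c("aid", "q1", "q2", "q3", "q4",
                                               "score", "rank")]),
    imaging = list(median_skew_pos = stats::median(skewPos, na.rm = TRUE),
                   median_skew_neg = stats::median(skewNeg, na.rm = TRUE),
                   fold = cmp$effect, p_adjusted = cmp$p_adjusted),
    photophysics = list(epsilon = eps$epsilon, tau = tau$tau, phi = phi),
    dose_response = list(ec50 = hf@ec50, hill = hf@hill, kd = kd$kd),
    checks = checks,
    pass = all(unlist(checks))
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Fetch PubChem BioAssay activity tables with fingerprints
#'
#' Downloads, for each assay identifier, the PubChem BioAssay activity CSV
#' and the CACTVS 881-bit substructure fingerprints of its compounds
#' (PUG-REST), and writes the package's standard assay CSV. Responses are
#' cached in `cacheDir`; a cached run makes no network calls. Network
#' failures and unknown AIDs raise errors naming the assay - results are
#' never silently partial.
#'
#' @param aids integer/character vector of assay identifiers.
#' @param cacheDir cache directory (created if needed).
#' @param outCsv path of the combined assay CSV to write.
#' @param minCompounds assay-inclusion rule applied after parsing (default
#'   20).
#' @return named list of [FingerprintAssay-class] objects (also written to
#'   `outCsv`).
#' @export
fetchPubChemAssays <- function(aids, cacheDir = "pubchem_cache",
                               outCsv = file.path(cacheDir, "assays.csv"),
                               minCompounds = 20L) {
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  assays <- list()
  for (aid in as.character(aids)) {
    csvFile <- file.path(cacheDir, sprintf("aid_%s.csv", aid))
    if (!file.exists(csvFile)) {
      url <- sprintf("https://pubchem.ncbi.nlm.nih.gov/rest/pug/assay/aid/%s/CSV", aid)
      ok <- tryCatch(utils::download.file(url, csvFile, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
      if (!identical(ok, 0L)) {
        unlink(csvFile)
        stopf("failed to download PubChem assay %s (unknown AID or no network)", aid)
      }
    }
    tab <- utils::read.csv(csvFile, check.names = FALSE)
    tab <- tab[suppressWarnings(!is.na(as.integer(tab$PUBCHEM_RESULT_TAG))), , drop = FALSE]
    acCol <- grep("ac50", names(tab), ignore.case = TRUE, value = TRUE)
    if (!length(acCol))
      stopf("assay %s: no AC50 column found in the activity table", aid)
    ac <- suppressWarnings(as.numeric(tab[[acCol[1L]]]))
    cid <- as.character(tab$PUBCHEM_CID)
    keep <- !is.na(ac) & ac > 0 & !is.na(cid) & nzchar(cid) & !duplicated(cid)
    nDrop <- sum(!keep)
    if (nDrop) message(sprintf("assay %s: dropped %d row(s) without numeric AC50/CID", aid, nDrop))
    cid <- cid[keep]; ac <- ac[keep]
    if (length(cid) < minCompounds)
      stopf("assay %s has %d usable compounds, below the inclusion minimum %d",
            aid, length(cid), minCompounds)
    fp <- fetchFingerprints(cid, cacheDir)
    assays[[aid]] <- FingerprintAssay(aid = aid, cid = cid,
                                      fingerprints = fp[cid, , drop = FALSE],
                                      ac50 = ac)
  }
  writeAssayCSV(assays, outCsv)
  assays
}

# CACTVS Fingerprint2D for a CID set, cached; rows named by CID
fetchFingerprints <- function(cids, cacheDir) {
  fpFile <- file.path(cacheDir, sprintf("fp_%s.csv", substr(digestCids(cids), 1, 12)))
  if (!file.exists(fpFile)) {
    rows <- list()
    for (chunk in split(cids, ceiling(seq_along(cids) / 100))) {
      url <- sprintf(
        "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/cid/%s/property/Fingerprint2D/CSV",
        paste(chunk, collapse = ","))
      tmp <- tempfile(fileext = ".csv")
      ok <- tryCatch(utils::download.file(url, tmp, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
      if (!identical(ok, 0L)) stopf("failed to download fingerprints for %d compounds", length(chunk))
      rows[[length(rows) + 1L]] <- utils::read.csv(tmp, colClasses = "character")
    }
    utils::write.csv(do.call(rbind, rows), fpFile, row.names = FALSE)
  }
  tab <- utils::read.csv(fpFile, colClasses = "character")
  fp <- t(vapply(tab$Fingerprint2D, decodeCactvsFingerprint, integer(881L)))
  rownames(fp) <- tab$CID
  fp
}

# stable short key for a CID set (no digest dependency)
digestCids <- function(cids) {
  s <- paste(cids, collapse = ",")
  paste0(length(cids), "_", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9)
}

#' Decode a CACTVS base64 2D fingerprint to 881 bits
#'
#' The base64 payload decodes to a 4-byte big-endian bit-length prefix
#' followed by the fingerprint bytes, most significant bit first.
#'
#' @param b64 base64 string (PubChem `Fingerprint2D` property).
#' @return integer vector of 881 zeros/ones.
#' @export
decodeCactvsFingerprint <- function(b64) {
  raw <- jsonlite::base64_dec(b64)
  if (length(raw) <= 4L) stopf("fingerprint payload too short")
  body <- raw[-(1:4)]
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L)  # little-endian per byte
  bits <- as.vector(bits[8:1, ])                           # MSB-first within byte
  bits[seq_len(881L)]
}
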