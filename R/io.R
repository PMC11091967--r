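# Shared format readers/writers: assay tables (CSV, SDF), single-plane TIFF
# images and 16-bit label masks, two-column spectrometer series, and curve
# tables.

#' Write assay tables to CSV
#'
#' Columns: `aid`, `cid`, `ac50_um`, `fp` (fingerprint as a 0/1 character
#' string, one character per bit).
#'
#' @param assays a [FingerprintAssay-class] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssayCSV <- function(assays, path) {
  if (is(assays, "FingerprintAssay")) assays <- list(assays)
  rows <- do.call(rbind, lapply(assays, function(a) data.frame(
    aid = a@aid, cid = a@cid, ac50_um = a@ac50,
    fp = apply(a@fingerprints, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read assay tables from CSV
#'
#' Inverse of [writeAssayCSV()]. Rows without a numeric positive AC50 are
#' dropped with a logged count.
#'
#' @param path CSV with columns `aid`, `cid`, `ac50_um`, `fp`.
#' @param fpLength expected fingerprint length (default 881).
#' @return named list of [FingerprintAssay-class] objects, one per `aid`.
#' @export
readAssayCSV <- function(path, fpLength = 881L) {
  tab <- utils::read.csv(path, colClasses = c(aid = "character", cid = "character",
                                              fp = "character"))
  need <- c("aid", "cid", "ac50_um", "fp")
  if (!all(need %in% names(tab)))
    stopf("assay CSV must have columns %s", paste(need, collapse = ", "))
  ac <- suppressWarnings(as.numeric(tab$ac50_um))
  bad <- is.na(ac) | ac <= 0
  if (any(bad)) {
    message(sprintf("readAssayCSV: dropped %d row(s) without a positive numeric AC50", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]; ac <- ac[!bad]
  }
  if (any(nchar(tab$fp) != fpLength))
    stopf("fingerprint strings must have %d characters", fpLength)
  out <- lapply(split(seq_len(nrow(tab)), tab$aid), function(idx) {
    fp <- t(vapply(strsplit(tab$fp[idx], ""), function(ch) as.integer(ch),
                   integer(fpLength)))
    FingerprintAssay(aid = tab$aid[idx][1L], cid = tab$cid[idx],
                     fingerprints = fp, ac50 = ac[idx])
  })
  out[order(names(out))]
}

#' Write assay tables to SDF
#'
#' Minimal V2000 records (zero atoms/bonds; the compounds are abstract
#' fingerprints, not structures) carrying `AID`, `CID`, `AC50_uM` and
#' `FINGERPRINT` data fields.
#'
#' @inheritParams writeAssayCSV
#' @return `path`, invisibly.
#' @export
writeAssaySDF <- function(assays, path) {
  if (is(assays, "FingerprintAssay")) assays <- list(assays)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (a in assays) {
    for (i in seq_along(a@cid)) {
      writeLines(c(
        a@cid[i], "  ProbeQuant", "",
        "  0  0  0  0  0  0  0  0  0  0999 V2000",
        "M  END",
        "> <AID>", a@aid, "",
        "> <CID>", a@cid[i], "",
        "> <AC50_uM>", format(a@ac50[i], digits = 12), "",
        "> <FINGERPRINT>", paste(a@fingerprints[i, ], collapse = ""), "",
        "$$$$"), con)
    }
  }
  invisible(path)
}

#' Write / read a single-plane intensity image as TIFF
#'
#' Intensities are stored as 32-bit floats on the 16-bit range (0..65535).
#'
#' @param img numeric matrix.
#' @param path TIFF file.
#' @return `path` invisibly (write); numeric matrix (read).
#' @export
writeChannelTiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeChannelTiff
#' @export
readChannelTiff <- function(path) {
  tiff::readTIFF(path) * 65535
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' @param mask integer matrix (0 = background; labels < 65536).
#' @param path TIFF file.
#' @return `path` invisibly (write); integer matrix (read).
#' @export
writeLabelMask <- function(mask, path) {
  if (max(mask) > 65535L) stopf("label values exceed the 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Read a two-column numeric series export
#'
#' Spectrometer/spectrophotometer exports: wavelength-vs-intensity,
#' time-vs-intensity or concentration-vs-absorbance CSV.
#'
#' @param path CSV with two numeric columns (header optional).
#' @param names column names for the result.
#' @return two-column numeric data.frame.
#' @export
readSeriesCSV <- function(path, names = c("x", "y")) {
  tab <- utils::read.csv(path, header = TRUE)
  if (ncol(tab) < 2L) stopf("series CSV must have two columns")
  tab <- tab[, 1:2]
  if (!all(vapply(tab, is.numeric, logical(1))))
    stopf("series columns must be numeric")
  stats::setNames(tab, names)
}

#' Write a long-format dose-response table to CSV
#'
#' @param curve data.frame from [simulateDoseResponse()] or with columns
#'   `concentration` and `response`/`ratio`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCurveCSV <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
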