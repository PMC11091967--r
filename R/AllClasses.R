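#' @import methods
NULL

#' FingerprintAssay: one bioassay's compounds
#'
#' Container for the compounds of a single activity assay: a binary
#' substructure-fingerprint matrix (compounds in rows, the PubChem 2D
#' convention uses 881 bits) together with half-maximal activity
#' concentrations (AC50, micromolar). This is the unit on which the quadrant
#' tolerance analysis operates.
#'
#' @slot aid character(1), assay identifier.
#' @slot cid character vector of compound identifiers (row names of the
#'   fingerprint matrix).
#' @slot fingerprints integer matrix of 0/1, one row per compound.
#' @slot ac50 numeric vector of AC50 values in micromolar, parallel to `cid`.
#'
#' @seealso [quadrantScore()], [readAssayCSV()], [simulateAssayLibrary()]
#' @export
setClass("FingerprintAssay",
  representation(
    aid = "character",
    cid = "character",
    fingerprints = "matrix",
    ac50 = "numeric"
  )
)

setValidity("FingerprintAssay", function(object) {
  msg <- character()
  if (length(object@aid) != 1L) msg <- c(msg, "'aid' must be length 1")
  n <- length(object@cid)
  if (nrow(object@fingerprints) != n)
    msg <- c(msg, "fingerprint rows must match number of compound ids")
  if (length(object@ac50) != n)
    msg <- c(msg, "'ac50' must be parallel to 'cid'")
  if (n > 0) {
    fp <- object@fingerprints
    if (!all(fp %in% c(0L, 1L)))
      msg <- c(msg, "fingerprints must contain only 0/1")
    if (any(!is.finite(object@ac50)) || any(object@ac50 <= 0))
      msg <- c(msg, "all AC50 values must be finite and > 0")
    if (anyDuplicated(object@cid))
      msg <- c(msg, "compound ids must be unique within an assay")
  }
  if (length(msg)) msg else TRUE
})

#' QuadrantScore: scaffold-tolerance statistic of one assay
#'
#' Result of the quadrant analysis: every non-reference compound of an assay
#' is placed in one of four quadrants of the (Tanimoto similarity to the most
#' potent compound) x (AC50) plane, and the tolerance score is the count of
#' potent-but-dissimilar compounds (Q3) over the non-potent compounds
#' (Q1 + Q2). A positive score flags a scaffold that keeps potency under
#' structural modification.
#'
#' @slot aid character(1) assay identifier.
#' @slot referenceCid character(1), the most potent compound (ties broken by
#'   smallest id; recorded in `tieBroken`).
#' @slot q1,q2,q3,q4 integer counts (dissimilar/non-potent,
#'   similar/non-potent, dissimilar/potent, similar/potent).
#' @slot score numeric(1); `q3/(q1+q2)`, `Inf` when the denominator is zero
#'   but q3 > 0 (see `infinite` flag), 0 when q3 = 0.
#' @slot infinite logical(1), TRUE when the score is the flagged-infinite case.
#' @slot potencyCutoff,similarityCutoff the cutoffs used (uM; Tanimoto).
#' @slot tieBroken logical(1), TRUE when the reference was chosen by id among
#'   tied minimal AC50s.
#' @export
setClass("QuadrantScore",
  representation(
    aid = "character",
    referenceCid = "character",
    q1 = "integer", q2 = "integer", q3 = "integer", q4 = "integer",
    score = "numeric",
    infinite = "logical",
    potencyCutoff = "numeric",
    similarityCutoff = "numeric",
    tieBroken = "logical"
  )
)

setValidity("QuadrantScore", function(object) {
  msg <- character()
  for (s in c("aid", "referenceCid", "score", "infinite"))
    if (length(slot(object, s)) != 1L) msg <- c(msg, sprintf("'%s' must be length 1", s))
  qs <- c(object@q1, object@q2, object@q3, object@q4)
  if (any(qs < 0L)) msg <- c(msg, "quadrant counts must be nonnegative")
  if (length(object@score) == 1L && is.finite(object@score) && object@score < 0)
    msg <- c(msg, "score must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ClusterModel: k-means partition of a compound set
#'
#' @slot k integer(1), number of clusters.
#' @slot labels integer vector of cluster indices in 1..k, named by compound id.
#' @slot centroids k x m numeric matrix.
#' @slot inertia numeric(1), total within-cluster sum of squares.
#' @slot inertiaCurve data.frame with columns `k`, `inertia` when a sweep was
#'   run (otherwise the single fitted point).
#' @slot representatives character vector, per-cluster compound id closest
#'   (Euclidean) to the cluster centroid.
#' @export
setClass("ClusterModel",
  representation(
    k = "integer",
    labels = "integer",
    centroids = "matrix",
    inertia = "numeric",
    inertiaCurve = "data.frame",
    representatives = "character"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L) msg <- c(msg, "'k' must be a single positive integer")
  if (length(object@labels) && (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (nrow(object@centroids) != object@k) msg <- c(msg, "centroids must have k rows")
  if (length(object@representatives) && length(object@representatives) != object@k)
    msg <- c(msg, "one representative per cluster required")
  if (length(msg)) msg else TRUE
})

#' HillFit: four-parameter logistic concentration-response fit
#'
#' Holds the result of a 4PL (Hill) fit: the half-maximal concentration
#' (EC50 for ascending, IC50 for descending curves), Hill coefficient and
#' asymptotes, with asymptotic standard errors from the Jacobian.
#'
#' @slot ec50,ec50SE numeric(1), half-maximal concentration and its SE, in the
#'   units of the fitted concentrations.
#' @slot hill,hillSE numeric(1), Hill coefficient (positive; the `direction`
#'   slot carries the curve orientation).
#' @slot top,bottom numeric(1), upper/lower asymptote in response units.
#' @slot direction character(1), "ascending" or "descending".
#' @slot converged logical(1).
#' @slot residualSS numeric(1), residual sum of squares.
#' @slot n integer(1), number of fitted points.
#' @export
setClass("HillFit",
  representation(
    ec50 = "numeric", ec50SE = "numeric",
    hill = "numeric", hillSE = "numeric",
    top = "numeric", bottom = "numeric",
    direction = "character",
    converged = "logical",
    residualSS = "numeric",
    n = "integer"
  )
)

setValidity("HillFit", function(object) {
  msg <- character()
  if (!(object@direction %in% c("ascending", "descending")))
    msg <- c(msg, "direction must be 'ascending' or 'descending'")
  if (length(object@ec50) != 1L || !is.finite(object@ec50) || object@ec50 <= 0)
    msg <- c(msg, "ec50 must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn FingerprintAssay constructor.
#' @param aid assay identifier.
#' @param cid compound identifiers.
#' @param fingerprints 0/1 matrix, one row per compound.
#' @param ac50 AC50 values, micromolar.
#' @export
FingerprintAssay <- function(aid, cid, fingerprints, ac50) {
  fingerprints <- as.matrix(fingerprints)
  storage.mode(fingerprints) <- "integer"
  rownames(fingerprints) <- as.character(cid)
  new("FingerprintAssay", aid = as.character(aid), cid = as.character(cid),
      fingerprints = fingerprints, ac50 = as.numeric(ac50))
}
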