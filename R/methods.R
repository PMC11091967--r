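# Generics, accessors and show methods for the S4 containers.

#' Assay identifier
#' @param x a ProbeQuant object.
#' @return character(1).
#' @export
setGeneric("aid", function(x) standardGeneric("aid"))

#' Compound identifiers
#' @param x a ProbeQuant object.
#' @return character vector.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Fingerprint matrix
#' @param x a ProbeQuant object.
#' @return 0/1 integer matrix, compounds in rows.
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))

#' AC50 values (micromolar)
#' @param x a ProbeQuant object.
#' @return numeric vector.
#' @export
setGeneric("ac50", function(x) standardGeneric("ac50"))

#' Tolerance score
#' @param x a QuadrantScore.
#' @return numeric(1); may be `Inf` (flagged-infinite case).
#' @export
setGeneric("toleranceScore", function(x) standardGeneric("toleranceScore"))

#' Quadrant counts
#' @param x a QuadrantScore.
#' @return named integer vector (q1..q4).
#' @export
setGeneric("quadrantCounts", function(x) standardGeneric("quadrantCounts"))

#' Cluster labels
#' @param x a ClusterModel.
#' @return integer vector in 1..k, named by compound id.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Per-cluster representative compounds
#' @param x a ClusterModel.
#' @return character vector, compound id closest to each centroid.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' Half-maximal concentration of a fitted curve
#' @param x a HillFit.
#' @return numeric(1), in the concentration units of the fit.
#' @export
setGeneric("ec50", function(x) standardGeneric("ec50"))

#' Hill coefficient of a fitted curve
#' @param x a HillFit.
#' @return numeric(1), positive.
#' @export
setGeneric("hillCoef", function(x) standardGeneric("hillCoef"))

#' @rdname aid
#' @export
setMethod("aid", "FingerprintAssay", function(x) x@aid)
#' @rdname aid
#' @export
setMethod("aid", "QuadrantScore", function(x) x@aid)
#' @rdname compoundIds
#' @export
setMethod("compoundIds", "FingerprintAssay", function(x) x@cid)
#' @rdname fingerprints
#' @export
setMethod("fingerprints", "FingerprintAssay", function(x) x@fingerprints)
#' @rdname ac50
#' @export
setMethod("ac50", "FingerprintAssay", function(x) x@ac50)
#' @rdname toleranceScore
#' @export
setMethod("toleranceScore", "QuadrantScore", function(x) x@score)
#' @rdname quadrantCounts
#' @export
setMethod("quadrantCounts", "QuadrantScore", function(x)
  c(q1 = x@q1, q2 = x@q2, q3 = x@q3, q4 = x@q4))
#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname representatives
#' @export
setMethod("representatives", "ClusterModel", function(x) x@representatives)
#' @rdname ec50
#' @export
setMethod("ec50", "HillFit", function(x) x@ec50)
#' @rdname hillCoef
#' @export
setMethod("hillCoef", "HillFit", function(x) x@hill)

#' Number of compounds in an assay
#' @param x a FingerprintAssay.
#' @export
setMethod("length", "FingerprintAssay", function(x) length(x@cid))

setMethod("show", "FingerprintAssay", function(object) {
  cat(sprintf("FingerprintAssay '%s': %d compounds, %d-bit fingerprints\n",
              object@aid, length(object@cid), ncol(object@fingerprints)))
  if (length(object@ac50)) {
    r <- range(object@ac50)
    cat(sprintf("  AC50 range: %.4g - %.4g uM\n", r[1], r[2]))
  }
})

setMethod("show", "QuadrantScore", function(object) {
  sc <- if (object@infinite) "Inf (no non-potent compounds)"
        else sprintf("%.4g", object@score)
  cat(sprintf(
    "QuadrantScore '%s': Q1=%d Q2=%d Q3=%d Q4=%d  score=%s\n  reference %s; cutoffs: potency %g uM, similarity %g\n",
    object@aid, object@q1, object@q2, object@q3, object@q4, sc,
    object@referenceCid, object@potencyCutoff, object@similarityCutoff))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k=%d, n=%d, inertia=%.4g\n",
              object@k, length(object@labels), object@inertia))
  if (length(object@representatives))
    cat("  representatives:", paste(object@representatives, collapse = ", "), "\n")
})

setMethod("show", "HillFit", function(object) {
  lbl <- if (object@direction == "ascending") "EC50" else "IC50"
  cat(sprintf("HillFit (%s): %s = %.4g +/- %.3g, hill = %.3g +/- %.3g\n",
              object@direction, lbl, object@ec50, object@ec50SE,
              object@hill, object@hillSE))
  cat(sprintf("  top = %.4g, bottom = %.4g, n = %d, converged = %s\n",
              object@top, object@bottom, object@n, object@converged))
})

#' Coerce a list of QuadrantScore objects to a data.frame
#'
#' @param x list of [QuadrantScore-class] objects.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with one row per assay: aid, reference_cid, q1..q4,
#'   score, infinite flag.
#' @export
quadrantScoreTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  stopifnot(all(vapply(x, is, logical(1), "QuadrantScore")))
  do.call(rbind, lapply(x, function(s) data.frame(
    aid = s@aid, reference_cid = s@referenceCid,
    q1 = s@q1, q2 = s@q2, q3 = s@q3, q4 = s@q4,
    score = s@score, infinite = s@infinite,
    stringsAsFactors = FALSE
  )))
}
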