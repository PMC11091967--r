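# Scaffold-tolerance analysis of ligand chemical space from substructure
# fingerprints: Tanimoto similarity, PCA embedding, cluster-number selection
# by the kneedle knee criterion, k-means clustering, and the quadrant
# tolerance score per assay.

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|` over the set bits of two equal-length binary
#' vectors. Symmetric, in \[0, 1\].
#'
#' @param a,b binary vectors (0/1 or logical) of equal length.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 2/4
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("fingerprints differ in length (%d vs %d)", length(a), length(b))
  a <- as.logical(a); b <- as.logical(b)
  if (anyNA(a) || anyNA(b)) stopf("fingerprints must not contain NA")
  un <- sum(a | b)
  if (un == 0L) stopf("Tanimoto similarity undefined: both fingerprints are all-zero")
  sum(a & b) / un
}

# Similarity of every row of a 0/1 matrix to one reference bit vector,
# by bit arithmetic (inter = M r, union = |M_i| + |r| - inter).
rowTanimoto <- function(M, ref) {
  ref <- as.numeric(ref)
  inter <- as.numeric(M %*% ref)
  un <- rowSums(M) + sum(ref) - inter
  out <- ifelse(un == 0, NA_real_, inter / un)
  out
}

#' Embed binary fingerprints by principal component analysis
#'
#' Centers the fingerprint columns and projects onto the first `d` principal
#' components. The sign of each component is fixed by forcing its
#' largest-magnitude loading positive, so the embedding is fully
#' deterministic.
#'
#' @param x 0/1 matrix (compounds in rows), a [FingerprintAssay-class], or a
#'   list of them (pooled).
#' @param d number of latent dimensions to retain (default 20).
#' @return list with class `"FingerprintEmbedding"`: `scores` (n x d),
#'   `explainedVarianceRatio` (length d, fraction of total variance per
#'   retained component), `d`, and `rotation`.
#' @export
embedFingerprints <- function(x, d = 20L) {
  M <- poolFingerprints(x)
  d <- assertCount(d, "d")
  if (nrow(M) < d)
    stopf("need at least d = %d rows for a %d-dimensional embedding, got %d", d, d, nrow(M))
  v <- apply(M, 2L, stats::var)
  if (all(v == 0)) {
    bad <- colnames(M)
    if (is.null(bad)) bad <- as.character(seq_len(ncol(M)))
    stopf("all fingerprint columns are constant (zero variance); first degenerate columns: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = d)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    scores = p$x,
    explainedVarianceRatio = evr[seq_len(min(d, length(evr)))],
    d = d,
    rotation = p$rotation
  ), class = "FingerprintEmbedding")
}

# rbind fingerprints out of the accepted input forms
poolFingerprints <- function(x) {
  if (is(x, "FingerprintAssay")) return(fingerprints(x))
  if (is.list(x) && length(x) && all(vapply(x, is, logical(1), "FingerprintAssay")))
    return(do.call(rbind, lapply(x, fingerprints)))
  M <- as.matrix(x)
  if (!all(M %in% c(0, 1))) stopf("fingerprint matrix must be binary (0/1)")
  storage.mode(M) <- "numeric"
  M
}

#' Compound-compound correlation matrix from an embedding
#'
#' Pearson correlation between the per-compound score vectors across the
#' first `nDims` latent dimensions. Compounds whose retained scores have zero
#' variance get `NA` rows/columns and are listed in the
#' `"flagged"` attribute.
#'
#' @param embedding result of [embedFingerprints()].
#' @param nDims number of leading dimensions to retain (default 10).
#' @return n x n symmetric correlation matrix with unit diagonal.
#' @export
compoundCorrelation <- function(embedding, nDims = 10L) {
  stopifnot(inherits(embedding, "FingerprintEmbedding"))
  nDims <- assertCount(nDims, "nDims")
  S <- embedding$scores
  if (nDims > ncol(S)) stopf("nDims = %d exceeds embedding dimension %d", nDims, ncol(S))
  S <- S[, seq_len(nDims), drop = FALSE]
  rowVar <- apply(S, 1L, stats::var)
  flagged <- which(rowVar == 0)
  R <- suppressWarnings(stats::cor(t(S)))
  diag(R) <- 1
  if (length(flagged)) {
    R[flagged, ] <- NA_real_
    R[, flagged] <- NA_real_
    diag(R)[flagged] <- 1
  }
  attr(R, "flagged") <- flagged
  R
}

#' Select the cluster number at the knee of an inertia curve
#'
#' Kneedle-type knee detection for a decreasing convex curve: both axes are
#' normalized to \[0, 1\] and the knee is the point maximizing the difference
#' between the normalized decrease and the normalized abscissa,
#' `D(k) = (1 - x_n) - y_n`. Deterministic.
#'
#' @param k strictly increasing integer vector of cluster counts (>= 4
#'   points).
#' @param inertia nonincreasing total within-cluster sums of squares,
#'   parallel to `k`.
#' @return the selected `k` (integer), with the difference curve in
#'   attribute `"difference"`.
#' @export
selectKneedle <- function(k, inertia) {
  if (length(k) != length(inertia)) stopf("'k' and 'inertia' must be parallel")
  if (length(k) < 4L) stopf("need at least 4 points to locate a knee")
  if (any(diff(k) <= 0)) stopf("'k' must be strictly increasing")
  if (any(diff(inertia) > 1e-8 * max(abs(inertia))))
    stopf("'inertia' must be nonincreasing in k")
  xn <- (k - k[1L]) / (k[length(k)] - k[1L])
  rng <- max(inertia) - min(inertia)
  if (rng == 0) stopf("inertia curve is flat: no knee")
  yn <- (inertia - min(inertia)) / rng
  D <- (1 - xn) - yn
  if (max(D) <= 1e-10)
    stopf("inertia curve is linear: no knee (fall back to the maximum-sensitivity k)")
  out <- as.integer(k[which.max(D)])
  attr(out, "difference") <- D
  out
}

#' Sweep k-means inertia over a range of cluster counts
#'
#' @param x numeric matrix, observations in rows.
#' @param ks integer vector of cluster counts to fit (default 2:15).
#' @param nInit random restarts per k (default 10).
#' @param seed RNG seed for the restarts.
#' @return data.frame with columns `k` and `inertia`.
#' @export
clusterSweep <- function(x, ks = 2:15, nInit = 10L, seed = 1L) {
  x <- as.matrix(x)
  ks <- sort(unique(as.integer(ks)))
  if (any(ks > nrow(x))) stopf("cannot fit k > n = %d rows", nrow(x))
  inertia <- withSeed(seed, vapply(ks, function(k)
    stats::kmeans(x, centers = k, nstart = nInit, iter.max = 50L)$tot.withinss,
    numeric(1)))
  data.frame(k = ks, inertia = inertia)
}

#' Cluster compounds by k-means
#'
#' Standard k-means with `nInit` restarts. The per-cluster representative is
#' the row with the smallest Euclidean distance to its centroid.
#'
#' @param x numeric matrix, compounds in rows (row names are compound ids).
#' @param k number of clusters (>= 2).
#' @param nInit random restarts (default 10).
#' @param seed RNG seed.
#' @return a [ClusterModel-class].
#' @export
clusterCompounds <- function(x, k, nInit = 10L, seed = 1L) {
  x <- as.matrix(x)
  k <- assertCount(k, "k", min = 2L)
  if (k > nrow(x)) stopf("k = %d exceeds the number of rows (%d)", k, nrow(x))
  if (k == nrow(x)) {
    # degenerate partition stats::kmeans refuses: every point is its own
    # cluster with zero inertia
    ids <- rownames(x); if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
    labels <- stats::setNames(seq_len(k), ids)
    return(new("ClusterModel", k = k, labels = labels, centroids = x,
               inertia = 0,
               inertiaCurve = data.frame(k = k, inertia = 0),
               representatives = ids))
  }
  km <- withSeed(seed, stats::kmeans(x, centers = k, nstart = nInit, iter.max = 50L))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  reps <- vapply(seq_len(k), function(cl) {
    idx <- which(km$cluster == cl)
    d2 <- rowSums((x[idx, , drop = FALSE] -
                     matrix(km$centers[cl, ], length(idx), ncol(x), byrow = TRUE))^2)
    ids[idx[which.min(d2)]]
  }, character(1))
  labels <- as.integer(km$cluster)
  names(labels) <- ids
  new("ClusterModel", k = k, labels = labels,
      centroids = km$centers, inertia = km$tot.withinss,
      inertiaCurve = data.frame(k = k, inertia = km$tot.withinss),
      representatives = reps)
}

#' Quadrant tolerance score of one assay
#'
#' Plots (conceptually) each compound's AC50 against its Tanimoto similarity
#' to the assay's most potent compound, and counts the four quadrants cut by
#' `potencyCutoff` and `similarityCutoff`:
#' Q1 dissimilar/non-potent, Q2 similar/non-potent, Q3 dissimilar/potent,
#' Q4 similar/potent. The tolerance score is `q3 / (q1 + q2)`; a positive
#' score means the scaffold retains potency under structural modification.
#'
#' @param assay a [FingerprintAssay-class].
#' @param potencyCutoff AC50 below which a compound counts as potent
#'   (micromolar; default 0.1).
#' @param similarityCutoff Tanimoto boundary between "similar" and
#'   "dissimilar" (default 0.8).
#' @param minCompounds assay-inclusion rule: error if the assay has fewer
#'   compounds (default 20); set to 0 to disable.
#' @return a [QuadrantScore-class].
#' @export
quadrantScore <- function(assay, potencyCutoff = 0.1, similarityCutoff = 0.8,
                          minCompounds = 20L) {
  stopifnot(is(assay, "FingerprintAssay"))
  n <- length(assay)
  if (n == 0L) stopf("assay '%s' is empty", assay@aid)
  if (n < minCompounds)
    stopf("assay '%s' has %d compounds, below the inclusion minimum of %d (set minCompounds = 0 to disable)",
          assay@aid, n, minCompounds)
  assertNumber(potencyCutoff, "potencyCutoff", lower = 0, closedLower = FALSE)
  assertNumber(similarityCutoff, "similarityCutoff", lower = 0, upper = 1)

  a <- ac50(assay)
  minA <- min(a)
  cand <- which(a == minA)
  tie <- length(cand) > 1L
  refIdx <- cand[orderCids(assay@cid[cand])][1L]
  ref <- fingerprints(assay)[refIdx, ]
  if (sum(ref) == 0L)
    stopf("reference compound '%s' has an all-zero fingerprint; similarity to it is undefined",
          assay@cid[refIdx])

  others <- setdiff(seq_len(n), refIdx)
  sim <- rowTanimoto(fingerprints(assay)[others, , drop = FALSE], ref)
  sim[is.na(sim)] <- 0  # all-zero compound vs nonzero reference: disjoint
  potent <- a[others] < potencyCutoff
  similar <- sim >= similarityCutoff
  q1 <- sum(!similar & !potent); q2 <- sum(similar & !potent)
  q3 <- sum(!similar & potent);  q4 <- sum(similar & potent)
  inf <- (q1 + q2) == 0L && q3 > 0L
  score <- if (q3 == 0L) 0 else if (inf) Inf else q3 / (q1 + q2)
  new("QuadrantScore", aid = assay@aid, referenceCid = assay@cid[refIdx],
      q1 = as.integer(q1), q2 = as.integer(q2),
      q3 = as.integer(q3), q4 = as.integer(q4),
      score = score, infinite = inf,
      potencyCutoff = potencyCutoff, similarityCutoff = similarityCutoff,
      tieBroken = tie)
}

# order compound ids numerically when they all parse as numbers, else
# lexicographically
orderCids <- function(cids) {
  num <- suppressWarnings(as.numeric(cids))
  if (!anyNA(num)) order(num) else order(cids)
}

#' Rank assays by tolerance score
#'
#' Descending by score with flagged-infinite scores first; ties broken by Q3
#' count (descending) then assay id (ascending).
#'
#' @param scores list of [QuadrantScore-class] objects (>= 1).
#' @return data.frame (one row per assay, best first) with columns `aid`,
#'   `reference_cid`, `q1`..`q4`, `score`, `infinite`, `rank`.
#' @export
rankAssays <- function(scores) {
  if (is(scores, "QuadrantScore")) scores <- list(scores)
  if (!length(scores)) stopf("need at least one score to rank")
  tab <- quadrantScoreTable(scores)
  ord <- order(-tab$score, -tab$q3, tab$aid)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Full scaffold analysis: embed, pick k, cluster, score, rank
#'
#' Convenience pipeline over a list of assays: pools all fingerprints, embeds
#' them (PCA), builds the compound correlation matrix, selects the cluster
#' number by the knee of the k-means inertia curve, fits the final k-means
#' model, scores every assay's quadrant tolerance and ranks them.
#'
#' @param assays list of [FingerprintAssay-class] objects.
#' @param d latent dimensions for the embedding (default 20).
#' @param nDims leading dimensions used for the correlation matrix and
#'   clustering (default 10).
#' @param kRange candidate cluster counts (default 2:15).
#' @param nInit k-means restarts (default 50). Restart misconvergence at
#'   larger k inflates single points of the inertia curve and corrupts the
#'   knee; 50 restarts keep the curve clean up to k around 12.
#' @param seed RNG seed for the clustering restarts.
#' @param clusterOn `"correlation"` clusters the rows of the
#'   compound-compound correlation matrix; `"scores"` clusters the
#'   `nDims`-dimensional PC scores directly.
#' @param potencyCutoff,similarityCutoff passed to [quadrantScore()].
#' @param minCompounds assay-inclusion minimum (default 20).
#' @return list: `embedding`, `correlation`, `inertiaCurve`, `k`, `model`,
#'   `scores` (list of QuadrantScore), `ranking` (data.frame).
#' @export
scaffoldAnalysis <- function(assays, d = 20L, nDims = 10L, kRange = 2:15,
                             nInit = 50L, seed = 1L,
                             clusterOn = c("correlation", "scores"),
                             potencyCutoff = 0.1, similarityCutoff = 0.8,
                             minCompounds = 20L) {
  clusterOn <- match.arg(clusterOn)
  emb <- embedFingerprints(assays, d = d)
  R <- compoundCorrelation(emb, nDims = nDims)
  X <- if (clusterOn == "correlation") {
    Xr <- R
    Xr[is.na(Xr)] <- 0
    Xr
  } else emb$scores[, seq_len(nDims), drop = FALSE]
  rownames(X) <- rownames(emb$scores)
  sweep <- clusterSweep(X, ks = kRange, nInit = nInit, seed = seed)
  # enforce monotonicity against restart noise before knee detection
  inert <- cummin(sweep$inertia)
  kStar <- selectKneedle(sweep$k, inert)
  model <- clusterCompounds(X, k = kStar, nInit = nInit, seed = seed)
  scores <- lapply(assays, quadrantScore, potencyCutoff = potencyCutoff,
                   similarityCutoff = similarityCutoff,
                   minCompounds = minCompounds)
  list(embedding = emb, correlation = R, inertiaCurve = sweep,
       k = as.integer(kStar), model = model, scores = scores,
       ranking = rankAssays(scores))
}
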