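# Independent brute-force oracles used to cross-check the implementation.

# Tanimoto by explicit set arithmetic on bit indices
bruteTanimoto <- function(a, b) {
  sa <- which(a != 0)
  sb <- which(b != 0)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# third standardized moment written as an explicit loop (no vectorized reuse
# of the implementation's expressions)
momentSkewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- 0; m3 <- 0
  for (v in x) {
    d <- v - m
    m2 <- m2 + d^2
    m3 <- m3 + d^3
  }
  (m3 / n) / (m2 / n)^1.5
}

# knee of a decreasing convex curve by brute-force maximization of the
# normalized difference, point by point
kneedleBrute <- function(k, inertia) {
  best <- NA_integer_; bestD <- -Inf
  for (i in seq_along(k)) {
    xn <- (k[i] - k[1]) / (k[length(k)] - k[1])
    yn <- (inertia[i] - min(inertia)) / (max(inertia) - min(inertia))
    D <- (1 - xn) - yn
    if (D > bestD) { bestD <- D; best <- k[i] }
  }
  best
}

# fraction of items whose cluster is the majority truth label of their
# assigned cluster
clusterPurity <- function(labels, truth) {
  tab <- table(labels, truth)
  sum(apply(tab, 1L, max)) / length(labels)
}

# small deterministic assay for hand-count examples
toyAssay <- function(ac50, fps, aid = "T1") {
  FingerprintAssay(aid = aid, cid = sprintf("c%02d", seq_along(ac50)),
                   fingerprints = fps, ac50 = ac50)
}
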