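# Shared fixtures: small, fast configurations used across test files.

# compact dyad configuration; 8 channels and short trials keep the
# average-reference perturbation and runtime small
quickConfig <- function(..., nChannels = 8L, fs = 500, duration = 20,
                        band = "alpha", noiseSd = 0.5, lineAmp = 0.5,
                        seed = 1L) {
  simulationConfig(nChannels = nChannels, fs = fs, duration = duration,
                   band = band, noiseSd = noiseSd, lineAmp = lineAmp,
                   seed = seed, ...)
}

# PLI of one channel pair after the full preprocessing chain
pipelinePli <- function(rec, band = "alpha", i = 1, j = 1) {
  ep <- preprocessDyad(rec, band)
  pa <- instantaneousPhase(ep$A)
  pb <- instantaneousPhase(ep$B)
  syncValues(interbrainMatrix(pa, pb))[i, j]
}

# random PLI-like null matrices for a paired cohort (both conditions drawn
# from the same distribution, so every edge null is exchangeable)
nullMatrices <- function(nDyads, nA = 8, nB = 8, lo = 0.05, hi = 0.45) {
  lapply(seq_len(nDyads), function(d) matrix(runif(nA * nB, lo, hi), nA, nB))
}

# plant a fixed offset on a set of edges in every dyad's matrix
plantEffect <- function(mats, edges, delta = 0.3) {
  lapply(mats, function(m) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      m[i, j] <- min(m[i, j] + delta, 1)
    }
    m
  })
}

# brute-force graph metric oracle: exhaustive triangle count and
# Floyd-Warshall all-pairs shortest paths, independent of graphMetrics()
oracleMetrics <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tri <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) {
    if (j != i && l != j && l != i && a[i, j] && a[j, l] && a[i, l])
      tri[i] <- tri[i] + 1
  }
  tri <- tri / 2
  denom <- k * (k - 1)
  clustering <- ifelse(denom > 0, 2 * tri / denom, 0)
  transitivity <- if (sum(denom) > 0) sum(2 * tri) / sum(denom) else 0
  fw <- function(adj) {
    m <- nrow(adj)
    d <- matrix(Inf, m, m)
    d[adj > 0] <- 1
    diag(d) <- 0
    for (kk in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m))
      if (d[i, kk] + d[kk, j] < d[i, j]) d[i, j] <- d[i, kk] + d[kk, j]
    d
  }
  eglob <- function(adj) {
    m <- nrow(adj)
    if (m < 2) return(0)
    d <- fw(adj)
    inv <- 1 / d; diag(inv) <- 0; inv[is.infinite(d)] <- 0
    sum(inv) / (m * (m - 1))
  }
  eloc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    eglob(a[nb, nb, drop = FALSE])
  }, numeric(1))
  list(degree = k, clustering = clustering, transitivity = transitivity,
       globalEfficiency = eglob(a), localEfficiency = eloc)
}

randomAdjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- rbinom(sum(up), 1, p)
  a + t(a)
}
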