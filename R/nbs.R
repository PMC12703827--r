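# Network-based statistic on interbrain matrices: paired edgewise t-maps,
# signed suprathreshold clustering on the bipartite cross-subject graph,
# and a within-dyad sign-flip permutation null of the maximum cluster mass
# giving family-wise-error corrected cluster p-values.

# stack a list of InterbrainMatrix (or plain matrices) into dyads x edges
.stackEdges <- function(mats) {
  getv <- function(m) if (is(m, "InterbrainMatrix")) m@values else m
  first <- getv(mats[[1]])
  out <- matrix(vapply(mats, function(m) as.numeric(getv(m)),
                       numeric(length(first))),
                nrow = length(mats), byrow = TRUE)
  attr(out, "dims") <- dim(first)
  out
}

#' Paired edgewise t-map between two conditions
#'
#' Per edge, a one-sample t of the within-dyad differences
#' \code{d_i = m1_i - m2_i}: \code{t = mean(d) * sqrt(n) / sd(d)}. An edge
#' with zero variance across dyads gets t = 0 with a warning (avoids
#' infinities from degenerate data). Edges missing in any dyad are NA.
#'
#' @param cond1Mats,cond2Mats lists of \linkS4class{InterbrainMatrix} (or
#'   plain matrices), one per dyad, same dyad order in both lists.
#' @param contrast character(2) condition names stored on the result.
#' @return an \linkS4class{EdgeTMap}.
#' @export
edgeT <- function(cond1Mats, cond2Mats, contrast = c("cond1", "cond2")) {
  if (length(cond1Mats) != length(cond2Mats))
    stop("paired design: both conditions need the same dyads")
  n <- length(cond1Mats)
  if (n < 2) stop("need at least 2 dyads")
  m1 <- .stackEdges(cond1Mats); m2 <- .stackEdges(cond2Mats)
  if (!identical(dim(m1), dim(m2))) stop("matrix shapes differ across conditions")
  d <- m1 - m2
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  t <- mu * sqrt(n) / sdv
  zeroVar <- !is.na(sdv) & sdv == 0
  if (any(zeroVar)) {
    warning(sprintf("%d edge(s) with zero variance across dyads; t set to 0",
                    sum(zeroVar)))
    t[zeroVar] <- 0
  }
  dims <- attr(m1, "dims")
  new("EdgeTMap", t = matrix(t, dims[1], dims[2]), df = n - 1,
      contrast = contrast)
}

# union-find over few edges; returns list of clusters (edge row indices)
.edgeComponents <- function(ij, nA) {
  # node ids: A channels 1..nA, B channels nA+1..nA+nB
  nodes <- c(ij[, 1], nA + ij[, 2])
  uid <- sort(unique(nodes))
  parent <- seq_along(uid)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  na <- match(ij[, 1], uid); nb <- match(nA + ij[, 2], uid)
  for (e in seq_len(nrow(ij))) {
    ra <- find(na[e]); rb <- find(nb[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(na, find, integer(1))
  split(seq_len(nrow(ij)), roots)
}

#' Signed suprathreshold clusters of an edge t-map
#'
#' Keeps edges with |t| >= \code{tCrit}, then finds connected components of
#' the bipartite graph whose vertices are subject-tagged channels/ROIs,
#' separately for positive and negative edges (signs never merge). The
#' graph is undirected, so connected and strongly connected components
#' coincide.
#'
#' @param tmap an \linkS4class{EdgeTMap} (or plain t matrix).
#' @param tCrit edge-inclusion threshold on |t|.
#' @return list of clusters: \code{edges} (two-column (row, col) matrix),
#'   \code{sign}, \code{mass} (sum of t over the cluster).
#' @export
suprathresholdClusters <- function(tmap, tCrit = 1.96) {
  t <- if (is(tmap, "EdgeTMap")) tmap@t else tmap
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(t) & sgn * t >= tCrit, arr.ind = TRUE)
    if (!nrow(idx)) next
    comps <- .edgeComponents(idx, nrow(t))
    for (rows in comps) {
      edges <- idx[rows, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        edges = unname(edges), sign = sgn,
        mass = sum(t[edges]))
    }
  }
  out
}

# fast max-|mass| over clusters for one permutation's t vector
.maxClusterMass <- function(tv, dims, tCrit) {
  best <- 0
  for (sgn in c(1, -1)) {
    sel <- which(sgn * tv >= tCrit)
    if (!length(sel)) next
    ij <- cbind((sel - 1L) %% dims[1] + 1L, (sel - 1L) %/% dims[1] + 1L)
    comps <- .edgeComponents(ij, dims[1])
    for (rows in comps) {
      m <- abs(sum(tv[sel[rows]]))
      if (m > best) best <- m
    }
  }
  best
}

#' Permutation null of the maximum cluster mass
#'
#' Each permutation flips the condition labels of a random subset of dyads
#' (equivalently sign-flips their difference vectors), recomputes the
#' edgewise t-map, clusters it, and records the maximum |sum of t| over
#' clusters (0 when nothing survives). When \code{2^nDyads <= nPerm} all
#' sign patterns are enumerated exhaustively and the seed is irrelevant.
#'
#' The sign flip leaves each edge's sum of squared differences unchanged,
#' so all permutation t-maps are computed in one matrix product.
#'
#' @param cond1Mats,cond2Mats per-dyad matrix lists as in
#'   \code{\link{edgeT}}.
#' @param nPerm number of permutations.
#' @param tCrit cluster-forming threshold on |t|.
#' @param seed integer seed for the sign-flip draw.
#' @return numeric vector of max-|mass| values, with attributes
#'   \code{exhaustive} and \code{nPerm}.
#' @export
permutationNull <- function(cond1Mats, cond2Mats, nPerm = 5000,
                            tCrit = 1.96, seed = 1L) {
  if (nPerm < 100) warning("fewer than 100 permutations: p-values unstable")
  n <- length(cond1Mats)
  m1 <- .stackEdges(cond1Mats); m2 <- .stackEdges(cond2Mats)
  dims <- attr(m1, "dims")
  d <- m1 - m2
  keep <- !colSums(is.na(d))            # drop missing edges before thresholding
  dk <- d[, keep, drop = FALSE]
  exhaustive <- 2^n <= nPerm
  if (exhaustive) {
    nTot <- as.integer(2^n)
    S <- matrix(1, nTot, n)
    for (j in seq_len(n))
      S[, j] <- ifelse(bitwAnd(seq_len(nTot) - 1L, bitwShiftL(1L, j - 1L)) > 0, -1, 1)
  } else {
    nTot <- as.integer(nPerm)
    set.seed(as.integer(seed))
    S <- matrix(sample(c(-1, 1), nTot * n, replace = TRUE), nTot, n)
  }
  ss <- colSums(dk^2)                   # flip-invariant second moment
  M <- (S %*% dk) / n
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Tm <- M * sqrt(n) / sqrt(pmax(V, 0))
  Tm[!is.finite(Tm)] <- 0
  # scatter back to full edge vector positions for clustering geometry
  full <- numeric(length(keep))
  null <- numeric(nTot)
  for (p in seq_len(nTot)) {
    full[] <- 0; full[keep] <- Tm[p, ]
    null[p] <- .maxClusterMass(full, dims, tCrit)
  }
  structure(null, exhaustive = exhaustive, nPerm = nTot)
}

#' Network-based statistic test between two paired conditions
#'
#' Observed signed suprathreshold clusters with FWER-corrected p-values
#' \code{p = (1 + #\{null >= |mass|\}) / (1 + nPerm)} against the
#' permutation null of the maximum cluster mass.
#'
#' @param cond1Mats,cond2Mats per-dyad matrix lists (paired).
#' @param nPerm permutations for the null.
#' @param tCrit cluster-forming threshold.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param contrast condition names.
#' @return an \linkS4class{NBSResult}.
#' @export
nbsTest <- function(cond1Mats, cond2Mats, nPerm = 5000, tCrit = 1.96,
                    alpha = 0.05, seed = 1L, contrast = c("cond1", "cond2")) {
  tmap <- edgeT(cond1Mats, cond2Mats, contrast)
  clusters <- suprathresholdClusters(tmap, tCrit)
  null <- permutationNull(cond1Mats, cond2Mats, nPerm = nPerm,
                          tCrit = tCrit, seed = seed)
  nTot <- attr(null, "nPerm")
  clusters <- lapply(clusters, function(cl) {
    cl$pFwer <- (1 + sum(null >= abs(cl$mass))) / (1 + nTot)
    cl
  })
  new("NBSResult", clusters = clusters, tCrit = tCrit,
      nullDistribution = as.numeric(null), nPerm = nTot,
      exhaustive = attr(null, "exhaustive"), alpha = alpha,
      seed = as.integer(seed))
}

#' Write significant NBS edges as a TSV
#'
#' @param result an \linkS4class{NBSResult}.
#' @param tmap the observed \linkS4class{EdgeTMap}.
#' @param path output file.
#' @param rowLabels,colLabels node labels for subjects A and B.
#' @return the table, invisibly.
#' @export
writeNbsEdges <- function(result, tmap, path, rowLabels = NULL,
                          colLabels = NULL) {
  t <- tmap@t
  if (is.null(rowLabels)) rowLabels <- sprintf("A%02d", seq_len(nrow(t)))
  if (is.null(colLabels)) colLabels <- sprintf("B%02d", seq_len(ncol(t)))
  rows <- list()
  for (i in seq_along(result@clusters)) {
    cl <- result@clusters[[i]]
    for (e in seq_len(nrow(cl$edges))) {
      r <- cl$edges[e, 1]; c <- cl$edges[e, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        nodeA = rowLabels[r], nodeB = colLabels[c], t = t[r, c],
        cluster_id = i, p_fwer = cl$pFwer, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nodeA = character(0), nodeB = character(0), t = numeric(0),
               cluster_id = integer(0), p_fwer = numeric(0))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
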