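# Binary graph-theoretic metrics of thresholded interbrain networks:
# nodal degree, clustering coefficient and local efficiency, plus global
# transitivity and efficiency, with per-brain-area aggregation.
#
# A purely interbrain (cross-subject) network is bipartite and therefore
# triangle-free: its clustering coefficients and transitivity are
# identically zero. Within-brain adjacency may be supplied in the same
# joint-node layout when triangle-based metrics are of interest.

#' Build a binary network from a thresholded interbrain matrix
#'
#' An edge is present wherever a surviving (nonzero, non-missing) entry
#' remains. Nodes are subject A's channels/ROIs followed by subject B's,
#' labels tagged "A:"/"B:".
#'
#' @param m a thresholded \linkS4class{InterbrainMatrix}.
#' @param areas optional character vector of area labels, one per
#'   channel/ROI side (recycled to both subjects), e.g. from
#'   \code{\link{dktAtlasTable}}.
#' @return a \linkS4class{BinaryNetwork}.
#' @export
binarize <- function(m, areas = NULL) {
  stopifnot(is(m, "InterbrainMatrix"))
  v <- m@values
  nA <- nrow(v); nB <- ncol(v)
  n <- nA + nB
  adj <- matrix(0, n, n)
  blk <- matrix(0, nA, nB)
  blk[!is.na(v) & v > 0] <- 1
  adj[seq_len(nA), nA + seq_len(nB)] <- blk
  adj[nA + seq_len(nB), seq_len(nA)] <- t(blk)
  labels <- c(paste0("A:", m@rowLabels), paste0("B:", m@colLabels))
  if (is.null(areas)) areas <- rep(NA_character_, nA)
  new("BinaryNetwork", adjacency = adj, nodeLabels = labels,
      nodeSubject = rep(c("A", "B"), c(nA, nB)),
      nodeArea = c(rep_len(areas, nA), rep_len(areas, nB)))
}

#' Graph metrics of a binary undirected network
#'
#' Standard binary-undirected definitions: degree as row sums; clustering
#' \code{C_i = 2 t_i / (k_i (k_i - 1))} with \code{t_i} triangles through i
#' (0 by convention when degree < 2); transitivity
#' \code{T = sum(2 t_i) / sum(k_i (k_i - 1))}; global efficiency as the
#' mean over ordered node pairs of 1/shortest-path-length with
#' \code{1/Inf = 0}; local efficiency of i as the global efficiency of the
#' subgraph induced by i's neighbors.
#'
#' @param net a \linkS4class{BinaryNetwork} or a symmetric 0/1 adjacency
#'   matrix.
#' @return a \linkS4class{GraphMetrics}.
#' @export
graphMetrics <- function(net) {
  a <- if (is(net, "BinaryNetwork")) net@adjacency else net
  labels <- if (is(net, "BinaryNetwork")) net@nodeLabels
            else sprintf("n%02d", seq_len(nrow(a)))
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes")
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  denom <- k * (k - 1)
  clustering <- ifelse(denom > 0, 2 * tri / denom, 0)
  transitivity <- if (sum(denom) > 0) sum(2 * tri) / sum(denom) else 0
  globalEfficiency <- .globalEfficiency(a)
  localEfficiency <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    .globalEfficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
  new("GraphMetrics", degree = as.numeric(k), clustering = clustering,
      localEfficiency = localEfficiency, transitivity = transitivity,
      globalEfficiency = globalEfficiency, nodeLabels = labels)
}

.globalEfficiency <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Aggregate nodal metrics by brain area and subject side
#'
#' Mean of each nodal metric over the nodes of each area, per subject.
#' Areas with no nodes on a side are reported as NA.
#'
#' @param metrics a \linkS4class{GraphMetrics}.
#' @param net the \linkS4class{BinaryNetwork} the metrics came from
#'   (provides node area and subject annotations).
#' @param areas optional explicit area levels (default: observed areas).
#' @return data.frame keyed by (subject, area) with mean degree,
#'   clustering and local efficiency.
#' @export
areaAggregate <- function(metrics, net, areas = NULL) {
  stopifnot(is(metrics, "GraphMetrics"), is(net, "BinaryNetwork"))
  av <- net@nodeArea
  if (all(is.na(av))) stop("network carries no area annotations")
  if (is.null(areas)) areas <- unique(av[!is.na(av)])
  rows <- list()
  for (side in c("A", "B")) {
    for (ar in areas) {
      sel <- net@nodeSubject == side & !is.na(av) & av == ar
      rows[[length(rows) + 1L]] <- data.frame(
        subject = side, area = ar,
        n_nodes = sum(sel),
        mean_degree = if (any(sel)) mean(metrics@degree[sel]) else NA_real_,
        mean_clustering = if (any(sel)) mean(metrics@clustering[sel]) else NA_real_,
        mean_local_efficiency =
          if (any(sel)) mean(metrics@localEfficiency[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
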