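# Cortex branch: standardized minimum-norm linear inverse (sLORETA-style)
# given a lead field, PCA reduction of source activity to atlas regions, and
# ROI-level interbrain PLV matrices.

#' Standardized minimum-norm source estimate
#'
#' Minimum-norm kernel \eqn{K = A^T (A A^T + \lambda H)^+} with H the
#' average-reference centering operator, raw estimate \eqn{\hat J = K y},
#' then sLORETA standardization: each source's estimate is divided by the
#' square root of the corresponding diagonal of the resolution projection
#' \eqn{S = K A}. In the noiseless single-source case the standardized
#' power attains its maximum at the true source (zero localization error).
#'
#' @param y channels x samples scalp data, average-referenced.
#' @param leadfield channels x sources gain matrix A.
#' @param lambda regularization >= 0; default
#'   \code{0.05 * trace(A A^T) / nChannels} (scale-free diagonal loading).
#' @param leadfieldId identifier stored on the result.
#' @return a \linkS4class{SourceEstimate}.
#' @export
sloretaInverse <- function(y, leadfield, lambda = NULL,
                           leadfieldId = "leadfield") {
  stopifnot(is.matrix(y), is.matrix(leadfield))
  if (nrow(y) != nrow(leadfield))
    stop("channel count of y must match lead-field rows")
  nc <- nrow(leadfield)
  G <- tcrossprod(leadfield)
  if (is.null(lambda)) lambda <- 0.05 * sum(diag(G)) / nc
  if (lambda < 0) stop("lambda must be >= 0")
  H <- diag(nc) - matrix(1 / nc, nc, nc)
  K <- t(leadfield) %*% MASS::ginv(G + lambda * H)
  Jhat <- K %*% y
  sdiag <- rowSums(K * t(leadfield))        # diag(K %*% A)
  scale <- sqrt(pmax(sdiag, 0))
  scale[scale < 1e-12 * max(scale)] <- Inf  # unresolvable sources -> 0
  act <- Jhat / scale
  new("SourceEstimate", activity = unname(act), lambda = lambda,
      leadfieldId = leadfieldId)
}

#' Reduce a source estimate to atlas-region time series
#'
#' Per region, the first principal component (covariance PCA across the
#' region's member sources, time as observations) of the member time
#' series. The component sign is fixed so that its correlation with the
#' region-mean series is non-negative, and each row is scaled to unit
#' variance.
#'
#' @param est a \linkS4class{SourceEstimate} (or sources x samples matrix).
#' @param fixture a \linkS4class{CortexFixture} providing the atlas, or an
#'   integer atlas vector.
#' @param fs sampling rate stored on the result (taken from the fixture if
#'   given).
#' @return a \linkS4class{ROISeries}.
#' @export
roiReduce <- function(est, fixture, fs = 250) {
  act <- if (is(est, "SourceEstimate")) est@activity else est
  if (is(fixture, "CortexFixture")) {
    atlas <- fixture@atlas; roiNames <- fixture@roiNames
    roiAreas <- fixture@roiAreas; fs <- fixture@fs
  } else {
    atlas <- as.integer(fixture)
    tab <- dktAtlasTable(); roiNames <- tab$roi; roiAreas <- tab$area
  }
  if (length(atlas) != nrow(act))
    stop("atlas must assign every source")
  if (length(unique(atlas)) != 62L)
    stop("every one of the 62 ROIs must contain at least one source")
  nT <- ncol(act)
  out <- matrix(0, 62L, nT)
  for (r in seq_len(62L)) {
    members <- act[atlas == r, , drop = FALSE]
    members <- members - rowMeans(members)
    if (nrow(members) == 1L) {
      pc <- members[1, ]
    } else {
      # first PC over time: leading eigenvector of the member covariance
      cv <- tcrossprod(members) / (nT - 1)
      ev <- eigen(cv, symmetric = TRUE)
      pc <- as.numeric(t(ev$vectors[, 1]) %*% members)
    }
    mu <- colMeans(members)
    if (sum(pc * mu) < 0) pc <- -pc
    s <- stats::sd(pc)
    out[r, ] <- if (s > 0) pc / s else pc
  }
  rownames(out) <- roiNames
  new("ROISeries", series = out, roiNames = roiNames, roiAreas = roiAreas,
      fs = fs)
}

#' ROI-level interbrain PLV matrix for a dyad
#'
#' Hilbert phase of each region series, then the time-averaged PLV over all
#' cross-subject region pairs (delegates to the scalar PLV entrywise).
#'
#' @param roiA,roiB \linkS4class{ROISeries} of subjects A and B, aligned in
#'   time.
#' @param band band label stored on the result.
#' @param condition,dyadIdent labels stored on the result.
#' @param trim seconds trimmed at each end before phase extraction.
#' @return a 62 x 62 \linkS4class{InterbrainMatrix} with metric "plv".
#' @export
cortexInterbrain <- function(roiA, roiB, band = "alpha", condition = "",
                             dyadIdent = "", trim = 1) {
  stopifnot(is(roiA, "ROISeries"), is(roiB, "ROISeries"))
  pa <- instantaneousPhase(roiA@series, fs = roiA@fs, band = band,
                           subjectRole = "A", sourceKind = "roi", trim = trim)
  pb <- instantaneousPhase(roiB@series, fs = roiB@fs, band = band,
                           subjectRole = "B", sourceKind = "roi", trim = trim)
  interbrainMatrix(pa, pb, metric = "plv", condition = condition,
                   dyadIdent = dyadIdent)
}
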