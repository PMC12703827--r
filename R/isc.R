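# Intersubject correlation via correlated component analysis: one shared
# projection w for both subjects, chosen to maximize the between-subject
# correlation of the projected series. The ISC score is the sum of the top
# three component correlations.

#' Fit correlated components to a dyad
#'
#' Solves the symmetric generalized eigenproblem
#' \deqn{(R_{AB} + R_{BA}) w = \rho (R_{AA} + R_{BB} + \gamma \tau I) w}
#' where the R are channel covariance matrices across time and
#' \eqn{\tau} is the mean diagonal of \eqn{R_{AA} + R_{BB}} (so the
#' shrinkage \eqn{\gamma} is scale-free). Eigenvalues are the component
#' correlations, eigenvectors the shared weights. The weight sign is fixed
#' by making each column's largest-magnitude entry positive.
#'
#' Average-referenced c-channel data has rank c - 1, so the pooled
#' covariance is singular at \eqn{\gamma = 0}; the default shrinkage keeps
#' the problem well posed.
#'
#' @param xA,xB channels x samples matrices of equal shape; centered
#'   internally.
#' @param shrinkage \eqn{\gamma \in [0, 1]}.
#' @return a \linkS4class{CorrelatedComponents}.
#' @export
corrcaFit <- function(xA, xB, shrinkage = 0.05) {
  stopifnot(is.matrix(xA), is.matrix(xB))
  if (!identical(dim(xA), dim(xB))) stop("xA and xB must have equal shape")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must lie in [0, 1]")
  nc <- nrow(xA); nt <- ncol(xA)
  if (nt <= nc) stop("need more samples than channels")
  xA <- xA - rowMeans(xA)
  xB <- xB - rowMeans(xB)
  Raa <- tcrossprod(xA) / (nt - 1)
  Rbb <- tcrossprod(xB) / (nt - 1)
  Rab <- tcrossprod(xA, xB) / (nt - 1)
  P <- Raa + Rbb
  tau <- mean(diag(P))
  B <- P + shrinkage * tau * diag(nc)
  eB <- eigen(B, symmetric = TRUE)
  tol <- 1e-10 * max(eB$values)
  if (any(eB$values < tol))
    stop(paste("pooled covariance is singular (average-referenced data is",
               "rank-deficient); use shrinkage > 0"))
  Bi2 <- eB$vectors %*% (t(eB$vectors) / sqrt(eB$values))   # B^{-1/2}
  Csym <- Rab + t(Rab)
  M <- t(Bi2) %*% Csym %*% Bi2
  M <- (M + t(M)) / 2
  eM <- eigen(M, symmetric = TRUE)
  ord <- order(eM$values, decreasing = TRUE)
  rho <- eM$values[ord]
  W <- Bi2 %*% eM$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  new("CorrelatedComponents", weights = W,
      correlations = pmin(pmax(rho, -1), 1), regularization = shrinkage)
}

#' Intersubject correlation score
#'
#' The sum of the first three component correlations. Requires at least
#' three components and a descending-sorted correlation vector; no silent
#' padding.
#'
#' @param components a \linkS4class{CorrelatedComponents}, or a numeric
#'   vector of sorted component correlations.
#' @return scalar ISC.
#' @export
iscScore <- function(components) {
  r <- if (is(components, "CorrelatedComponents"))
    components@correlations else components
  if (length(r) < 3) stop("ISC needs at least 3 components")
  if (any(diff(r) > 1e-12))
    stop("component correlations must be sorted in descending order")
  sum(r[1:3])
}

#' ISC table over a dyad cohort with a paired condition contrast
#'
#' Computes one ISC value per (dyad, condition, band) from preprocessed
#' trials, the per-band condition means, and a paired two-tailed t-test
#' between two designated conditions within each band.
#'
#' @param cohort nested list: dyad -> condition ->
#'   \linkS4class{DyadRecording}.
#' @param bands character vector of band names.
#' @param contrast character(2): the two condition labels to compare
#'   (paired within dyads).
#' @param shrinkage passed to \code{\link{corrcaFit}}.
#' @param trialLength seconds per trial (NULL: whole recording).
#' @return list with \code{table} (data.frame dyad/condition/band/isc),
#'   \code{means} (band x condition), \code{tests} (per band: t, df, p,
#'   mean difference).
#' @export
iscConditionTable <- function(cohort, bands = "alpha",
                              contrast = c("F", "N"), shrinkage = 0.05,
                              trialLength = NULL) {
  if (!length(cohort)) stop("need at least 1 dyad")
  rows <- list()
  for (nm in names(cohort)) {
    for (cond in names(cohort[[nm]])) {
      rec <- cohort[[nm]][[cond]]
      for (b in bands) {
        ep <- preprocessDyad(rec, b, conditionLabel = cond,
                             trialLength = trialLength)
        cc <- corrcaFit(ep$A@data, ep$B@data, shrinkage = shrinkage)
        rows[[length(rows) + 1L]] <- data.frame(
          dyad = nm, condition = cond, band = b, isc = iscScore(cc),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  means <- tapply(tab$isc, list(band = tab$band, condition = tab$condition),
                  mean)
  tests <- list()
  if (!is.null(contrast)) {
    for (b in bands) {
      x1 <- tab$isc[tab$band == b & tab$condition == contrast[1]]
      x2 <- tab$isc[tab$band == b & tab$condition == contrast[2]]
      d1 <- tab$dyad[tab$band == b & tab$condition == contrast[1]]
      d2 <- tab$dyad[tab$band == b & tab$condition == contrast[2]]
      if (length(x1) != length(x2) || !identical(sort(d1), sort(d2)))
        stop("unbalanced pairing: each dyad needs both contrast conditions")
      x2 <- x2[match(d1, d2)]
      if (length(x1) < 2)
        stop("paired test needs at least 2 dyads (df = 0 otherwise)")
      d <- x1 - x2
      if (stats::sd(d) == 0 && mean(d) == 0) {
        # degenerate but well-defined: no difference anywhere
        tests[[b]] <- list(t = 0, df = length(d) - 1, p = 1, meanDiff = 0)
      } else {
        tt <- stats::t.test(x1, x2, paired = TRUE)
        tests[[b]] <- list(t = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p = tt$p.value, meanDiff = unname(tt$estimate))
      }
    }
  }
  list(table = tab, means = means, tests = tests)
}
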