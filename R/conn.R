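# Interbrain functional connectivity: instantaneous phase via the Hilbert
# analytic signal, the phase lag index (PLI) for scalp channels, the
# time-averaged phase locking value (PLV) for cortical ROIs, matrix assembly
# over all cross-subject pairs, and proportional/absolute thresholding.

#' Instantaneous phase of a band-limited trial
#'
#' Phase of the FFT-based analytic signal per channel. The first and last
#' second are trimmed (Hilbert edge effects); an all-zero channel has no
#' defined phase and is masked rather than propagating NaN.
#'
#' @param x an \linkS4class{EpochedBand}, or a channels x samples matrix.
#' @param fs sampling rate (taken from the object when \code{x} is an
#'   \linkS4class{EpochedBand}).
#' @param band,subjectRole,sourceKind metadata when \code{x} is a bare
#'   matrix.
#' @param trim seconds discarded at each end.
#' @return a \linkS4class{PhaseSeries}.
#' @export
instantaneousPhase <- function(x, fs = NULL, band = "alpha",
                               subjectRole = "A", sourceKind = "scalp",
                               trim = 1) {
  if (is(x, "EpochedBand")) {
    fs <- x@fs; band <- x@band; subjectRole <- x@subjectRole
    x <- x@data
  }
  if (is.null(fs)) stop("fs required for matrix input")
  nTrim <- as.integer(round(trim * fs))
  n <- ncol(x)
  if (n <= 2 * nTrim) stop("trial too short for the edge trim")
  keep <- (nTrim + 1L):(n - nTrim)
  mask <- apply(x, 1L, function(ch) all(ch == 0))
  ph <- matrix(0, nrow(x), length(keep))
  for (ch in which(!mask))
    ph[ch, ] <- Arg(analyticSignal(x[ch, ]))[keep]
  rownames(ph) <- rownames(x)
  new("PhaseSeries", phase = ph, fs = fs, band = band,
      subjectRole = subjectRole, sourceKind = sourceKind, mask = mask)
}

#' Phase lag index of two phase series
#'
#' \code{PLI = | mean_t sign(sin(phi_a(t) - phi_b(t))) |} with
#' \code{sign(0) = 0}, so consistent nonzero-lag phase differences give 1
#' while zero-lag (volume-conduction-like) synchrony gives 0. Symmetric in
#' its arguments.
#'
#' @param phaseA,phaseB numeric phase vectors of equal length >= 2, radians.
#' @return scalar in [0, 1].
#' @export
pli <- function(phaseA, phaseB) {
  if (length(phaseA) != length(phaseB)) stop("phase series length mismatch")
  if (length(phaseA) < 2) stop("need at least 2 samples")
  abs(mean(sign(sin(phaseA - phaseB))))
}

#' Time-averaged phase locking value of two phase series
#'
#' \code{PLV = | mean_t exp(i (phi_a(t) - psi_b(t))) |}: 1 for a perfectly
#' consistent phase difference at any lag (including zero), near 0 for
#' independent phases. Symmetric in its arguments.
#'
#' @param phaseA,phaseB numeric phase vectors of equal length >= 2, radians.
#' @return scalar in [0, 1].
#' @export
plv <- function(phaseA, phaseB) {
  if (length(phaseA) != length(phaseB)) stop("phase series length mismatch")
  if (length(phaseA) < 2) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phaseA - phaseB))))
}

#' Interbrain synchronization matrix of a dyad trial
#'
#' Entry (j, k) is \code{metric(phase_A[j], phase_B[k])} over all
#' cross-subject pairs; within-subject pairs are never computed. PLI is the
#' scalp default and PLV the cortex (ROI) default; overriding the pairing
#' requires \code{force = TRUE}.
#'
#' @param phasesA,phasesB \linkS4class{PhaseSeries} of subjects A and B,
#'   aligned in time.
#' @param metric "pli" or "plv"; defaults by \code{sourceKind}.
#' @param force allow a metric/source-kind combination other than the
#'   default.
#' @param condition,dyadIdent labels stored on the result.
#' @return an \linkS4class{InterbrainMatrix}; pairs involving a masked
#'   channel are NA.
#' @export
interbrainMatrix <- function(phasesA, phasesB, metric = NULL, force = FALSE,
                             condition = "", dyadIdent = "") {
  stopifnot(is(phasesA, "PhaseSeries"), is(phasesB, "PhaseSeries"))
  if (ncol(phasesA@phase) != ncol(phasesB@phase))
    stop("phase series are not aligned in time")
  kind <- phasesA@sourceKind
  default <- if (kind == "scalp") "pli" else "plv"
  if (is.null(metric)) metric <- default
  if (metric != default && !force)
    stop(sprintf(
      "metric '%s' is not the default for %s data; pass force = TRUE to override",
      metric, kind))
  fn <- if (metric == "pli") pli else plv
  nA <- nrow(phasesA@phase); nB <- nrow(phasesB@phase)
  v <- matrix(NA_real_, nA, nB)
  for (j in seq_len(nA)) {
    if (phasesA@mask[j]) next
    pj <- phasesA@phase[j, ]
    for (k in seq_len(nB)) {
      if (phasesB@mask[k]) next
      v[j, k] <- fn(pj, phasesB@phase[k, ])
    }
  }
  labA <- rownames(phasesA@phase); labB <- rownames(phasesB@phase)
  if (is.null(labA)) labA <- sprintf("ch%02d", seq_len(nA))
  if (is.null(labB)) labB <- sprintf("ch%02d", seq_len(nB))
  new("InterbrainMatrix", values = v, metric = metric,
      rowLabels = labA, colLabels = labB, band = phasesA@band,
      condition = condition, dyadId = dyadIdent)
}

#' Threshold an interbrain matrix
#'
#' Removes trivial connections. Proportional rule: keep the strongest
#' fraction \code{p} of (non-missing) entries, \code{ceiling(p * n)} of
#' them, zeroing the rest; ties at the cutoff are all kept. Absolute rule:
#' keep entries \code{>= tau}.
#'
#' @param m an \linkS4class{InterbrainMatrix}.
#' @param rule "proportional" or "absolute".
#' @param p fraction kept under the proportional rule, in (0, 1].
#' @param tau absolute cutoff under the absolute rule.
#' @return the thresholded \linkS4class{InterbrainMatrix}.
#' @export
thresholdMatrix <- function(m, rule = c("proportional", "absolute"),
                            p = 0.2, tau = NULL) {
  stopifnot(is(m, "InterbrainMatrix"))
  rule <- match.arg(rule)
  v <- m@values
  if (rule == "proportional") {
    if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
    obs <- v[!is.na(v)]
    keepN <- ceiling(p * length(obs))
    cutoff <- sort(obs, decreasing = TRUE)[keepN]
    v[!is.na(v) & v < cutoff] <- 0
  } else {
    if (is.null(tau)) stop("tau required for the absolute rule")
    v[!is.na(v) & v < tau] <- 0
  }
  initialize(m, values = v)
}
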