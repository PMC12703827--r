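#' @import methods
NULL

#' Simulation configuration for a synthetic dyad
#'
#' Parameters of the coupled-oscillator dyad generator: channel count and
#' sampling rate of the virtual amplifiers, trial duration, the frequency band
#' the planted oscillation lives in, which cross-subject channel pairs are
#' phase-coupled, the coupling concentration and mean lag, and the amplitudes
#' of the pink-noise background and 50 Hz line contaminant.
#'
#' @slot nChannels integer, channels per subject.
#' @slot fs numeric, sampling rate in Hz.
#' @slot duration numeric, trial length in seconds.
#' @slot band character, one of \code{"delta"}, \code{"theta"}, \code{"alpha"},
#'   \code{"beta"}.
#' @slot coupledPairs two-column integer matrix of (channel A, channel B)
#'   pairs carrying interbrain coupling.
#' @slot kappa numeric >= 0, von Mises concentration of the phase-difference
#'   jitter (0 = independent, large = rigid locking).
#' @slot lag numeric, mean phase difference (radians) of coupled pairs.
#' @slot noiseSd numeric, standard deviation of the 1/f background (uV).
#' @slot lineAmp numeric, amplitude of the 50 Hz line sinusoid (uV).
#' @slot seed integer random seed.
#' @export
setClass("SimulationConfig",
  representation(
    nChannels = "integer", fs = "numeric", duration = "numeric",
    band = "character", coupledPairs = "matrix", kappa = "numeric",
    lag = "numeric", noiseSd = "numeric", lineAmp = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  if (!object@band %in% names(bandTable()))
    msg <- c(msg, sprintf("unknown band '%s' (use %s)", object@band,
                          paste(names(bandTable()), collapse = "/")))
  if (object@kappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@lineAmp < 0) msg <- c(msg, "lineAmp must be >= 0")
  if (object@lag < 0 || object@lag >= pi)
    msg <- c(msg, "lag must lie in [0, pi)")
  cp <- object@coupledPairs
  if (nrow(cp) > 0) {
    if (ncol(cp) != 2) msg <- c(msg, "coupledPairs must have two columns")
    else {
      if (any(cp < 1) || any(cp > object@nChannels))
        msg <- c(msg, "coupledPairs indices out of channel range")
      if (anyDuplicated(cp))
        msg <- c(msg, "coupledPairs contains duplicate pairs")
      if (anyDuplicated(cp[, 2]))
        msg <- c(msg, paste("each subject-B channel can follow at most one",
                            "subject-A channel"))
    }
  }
  if (object@band %in% names(bandTable())) {
    lo <- bandTable()[[object@band]][1]
    # at least 10 cycles of the band's low edge, else band filtering is moot
    if (object@duration * lo < 10)
      msg <- c(msg, sprintf(
        "duration %.3g s too short: need >= 10 cycles of %g Hz",
        object@duration, lo))
  }
  if (length(msg)) msg else TRUE
})

#' Simultaneous two-subject EEG recording
#'
#' Container for one dyad: two channels-by-samples voltage matrices recorded
#' against a common clock, shared channel labels, and event marks delimiting
#' condition trials.
#'
#' @slot dataA,dataB numeric matrices (channels x samples), microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of montage labels.
#' @slot events data.frame with columns \code{sample} (0-based index) and
#'   \code{label}.
#' @slot dyadId character identifier.
#' @export
setClass("DyadRecording",
  representation(
    dataA = "matrix", dataB = "matrix", fs = "numeric",
    channelLabels = "character", events = "data.frame", dyadId = "character"
  )
)

setValidity("DyadRecording", function(object) {
  msg <- character(0)
  if (!identical(dim(object@dataA), dim(object@dataB)))
    msg <- c(msg, "dataA and dataB must have identical shape (simultaneous recording)")
  if (length(object@channelLabels) != nrow(object@dataA))
    msg <- c(msg, "channelLabels length must equal channel count")
  if (nrow(object@events) > 0) {
    if (!all(c("sample", "label") %in% names(object@events)))
      msg <- c(msg, "events needs columns 'sample' and 'label'")
    else if (any(object@events$sample < 0) ||
             any(object@events$sample >= ncol(object@dataA)))
      msg <- c(msg, "event sample indices must lie in [0, n_samples)")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Toy forward model for the cortex branch
#'
#' A lead-field gain matrix mapping cortical sources to scalp channels
#' (Y = A X), a sources-by-samples activity matrix, and an atlas assigning
#' every source to one of 62 cortical regions grouped into 7 areas.
#'
#' @slot leadfield channels x sources gain matrix; every column sums to zero
#'   across channels (average-referenced sensor space).
#' @slot sourceActivity sources x samples matrix.
#' @slot atlas integer vector, source index -> ROI index in 1..62.
#' @slot roiNames character(62) region labels.
#' @slot roiAreas character(62) area group of each region.
#' @slot fs sampling rate of the source activity.
#' @export
setClass("CortexFixture",
  representation(
    leadfield = "matrix", sourceActivity = "matrix", atlas = "integer",
    roiNames = "character", roiAreas = "character", fs = "numeric"
  )
)

setValidity("CortexFixture", function(object) {
  msg <- character(0)
  if (length(object@atlas) != ncol(object@leadfield))
    msg <- c(msg, "atlas must assign every lead-field column (source) to a ROI")
  if (length(object@roiNames) != 62L)
    msg <- c(msg, "exactly 62 ROI names required")
  if (length(object@roiAreas) != 62L)
    msg <- c(msg, "exactly 62 ROI area labels required")
  if (length(object@atlas) &&
      (any(object@atlas < 1L) || any(object@atlas > 62L)))
    msg <- c(msg, "atlas indices must lie in 1..62")
  if (length(object@atlas) && length(unique(object@atlas)) != 62L)
    msg <- c(msg, "every one of the 62 ROIs must contain at least one source")
  if (nrow(object@sourceActivity) != ncol(object@leadfield))
    msg <- c(msg, "sourceActivity rows must match lead-field columns")
  # columns must live in the average-reference subspace and the lead field
  # must retain the maximal rank attainable there
  cs <- colSums(object@leadfield)
  if (any(abs(cs) > 1e-8 * max(abs(object@leadfield))))
    msg <- c(msg, "lead-field columns must sum to zero across channels")
  maxRank <- min(nrow(object@leadfield) - 1L, ncol(object@leadfield))
  if (qr(object@leadfield)$rank < maxRank)
    msg <- c(msg, "lead field rank-deficient beyond the average-reference null space")
  if (length(msg)) msg else TRUE
})

#' Band-limited, preprocessed single-subject trial
#'
#' Output of the preprocessing chain for one subject, one condition and one
#' band: 250 Hz, average-referenced, zero-phase band-passed.
#'
#' @slot data channels x samples matrix.
#' @slot fs sampling rate (Hz).
#' @slot band band name.
#' @slot bandEdges numeric(2) low/high cutoff in Hz.
#' @slot conditionLabel condition the trial belongs to.
#' @slot subjectRole "A" or "B".
#' @slot dyadId dyad identifier.
#' @export
setClass("EpochedBand",
  representation(
    data = "matrix", fs = "numeric", band = "character",
    bandEdges = "numeric", conditionLabel = "character",
    subjectRole = "character", dyadId = "character"
  )
)

setValidity("EpochedBand", function(object) {
  msg <- character(0)
  known <- bandTable()
  if (!object@band %in% names(known))
    msg <- c(msg, "band must be one of delta/theta/alpha/beta")
  else if (!isTRUE(all.equal(object@bandEdges, known[[object@band]])))
    msg <- c(msg, "bandEdges must match the canonical band table")
  scale <- max(abs(object@data), 1e-12)
  if (nrow(object@data) >= 2 &&
      max(abs(colMeans(object@data))) > 1e-9 * scale)
    msg <- c(msg, "data must be average-referenced (per-sample channel mean ~ 0)")
  if (!object@subjectRole %in% c("A", "B"))
    msg <- c(msg, "subjectRole must be 'A' or 'B'")
  if (length(msg)) msg else TRUE
})

#' Instantaneous phase of a band-limited trial
#'
#' @slot phase channels x samples matrix of radians in (-pi, pi].
#' @slot fs sampling rate (Hz).
#' @slot band band name.
#' @slot subjectRole "A" or "B".
#' @slot sourceKind "scalp" or "roi".
#' @slot mask logical vector; TRUE marks channels whose phase is undefined
#'   (e.g. an all-zero channel) and must be treated as missing downstream.
#' @export
setClass("PhaseSeries",
  representation(
    phase = "matrix", fs = "numeric", band = "character",
    subjectRole = "character", sourceKind = "character", mask = "logical"
  )
)

setValidity("PhaseSeries", function(object) {
  msg <- character(0)
  ok <- object@phase[!object@mask, , drop = FALSE]
  if (length(ok) && (any(ok <= -pi - 1e-9) || any(ok > pi + 1e-9)))
    msg <- c(msg, "phase values must lie in (-pi, pi]")
  if (length(object@mask) != nrow(object@phase))
    msg <- c(msg, "mask length must equal channel count")
  if (!object@sourceKind %in% c("scalp", "roi"))
    msg <- c(msg, "sourceKind must be 'scalp' or 'roi'")
  if (length(msg)) msg else TRUE
})

#' Interbrain synchronization matrix
#'
#' Cross-subject block only: entry (j, k) is the synchronization between
#' channel/ROI j of subject A and channel/ROI k of subject B. Within-subject
#' connectivity is deliberately excluded.
#'
#' @slot values n_A x n_B matrix with entries in [0, 1]; NA marks pairs
#'   involving a masked channel.
#' @slot metric "pli" or "plv".
#' @slot rowLabels,colLabels channel/ROI labels of subjects A and B.
#' @slot band band name.
#' @slot condition condition label.
#' @slot dyadId dyad identifier.
#' @export
setClass("InterbrainMatrix",
  representation(
    values = "matrix", metric = "character", rowLabels = "character",
    colLabels = "character", band = "character", condition = "character",
    dyadId = "character"
  )
)

setValidity("InterbrainMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (any(!is.na(v) & (v < -1e-9 | v > 1 + 1e-9)))
    msg <- c(msg, "all entries must lie in [0, 1]")
  if (!object@metric %in% c("pli", "plv"))
    msg <- c(msg, "metric must be 'pli' or 'plv'")
  if (length(object@rowLabels) != nrow(v) || length(object@colLabels) != ncol(v))
    msg <- c(msg, "label lengths must match matrix dimensions")
  if (length(msg)) msg else TRUE
})

#' Correlated component decomposition of a dyad
#'
#' Shared projection vectors maximizing between-subject correlation, with the
#' component correlations sorted in descending order. The intersubject
#' correlation (ISC) score is the sum of the first three correlations.
#'
#' @slot weights channels x k projection matrix shared by the two subjects.
#' @slot correlations numeric(k), sorted descending, each in [-1, 1].
#' @slot regularization shrinkage parameter used for the pooled covariance.
#' @export
setClass("CorrelatedComponents",
  representation(
    weights = "matrix", correlations = "numeric", regularization = "numeric"
  )
)

setValidity("CorrelatedComponents", function(object) {
  msg <- character(0)
  r <- object@correlations
  if (is.unsorted(rev(r), strictly = FALSE) && is.unsorted(-r))
    msg <- c(msg, "correlations must be sorted descending")
  if (any(abs(r) > 1 + 1e-9))
    msg <- c(msg, "|correlation| must be <= 1")
  if (ncol(object@weights) != length(r))
    msg <- c(msg, "one weight column per component required")
  if (length(msg)) msg else TRUE
})

#' Standardized distributed source estimate
#'
#' @slot activity sources x samples standardized amplitudes.
#' @slot lambda regularization used in the minimum-norm kernel.
#' @slot leadfieldId identifier of the lead field used.
#' @export
setClass("SourceEstimate",
  representation(
    activity = "matrix", lambda = "numeric", leadfieldId = "character"
  )
)

setValidity("SourceEstimate", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@activity)))
    msg <- c(msg, "activity must be finite everywhere")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-region cortical time series
#'
#' One row per atlas region: the first principal component of that region's
#' member-source time series, sign-aligned with the region mean and scaled to
#' unit variance.
#'
#' @slot series 62 x samples matrix.
#' @slot roiNames character(62).
#' @slot roiAreas character(62) area group per region.
#' @slot fs sampling rate (Hz).
#' @export
setClass("ROISeries",
  representation(
    series = "matrix", roiNames = "character", roiAreas = "character",
    fs = "numeric"
  )
)

setValidity("ROISeries", function(object) {
  msg <- character(0)
  if (nrow(object@series) != 62L) msg <- c(msg, "exactly 62 rows required")
  if (length(object@roiNames) != 62L || length(object@roiAreas) != 62L)
    msg <- c(msg, "62 ROI names and areas required")
  v <- apply(object@series, 1, stats::var)
  if (any(abs(v - 1) > 1e-6 & v > 0))
    msg <- c(msg, "each ROI series must have unit variance")
  if (length(msg)) msg else TRUE
})

#' Paired edgewise t-statistic map
#'
#' @slot t n_A x n_B matrix of paired t statistics.
#' @slot df degrees of freedom (n_dyads - 1).
#' @slot contrast character(2), names of the contrasted conditions.
#' @export
setClass("EdgeTMap",
  representation(t = "matrix", df = "numeric", contrast = "character")
)

#' Network-based statistic result
#'
#' Signed suprathreshold edge clusters on the bipartite interbrain graph with
#' family-wise-error corrected p-values from a within-dyad sign-flip
#' permutation null of the maximum cluster mass.
#'
#' @slot clusters list; each element has \code{edges} (two-column matrix of
#'   (row, col) indices), \code{sign} (+1/-1), \code{mass} (sum of t over the
#'   cluster's edges), \code{pFwer}.
#' @slot tCrit edge-inclusion threshold on |t|.
#' @slot nullDistribution max-|mass| per permutation.
#' @slot nPerm number of permutations (or enumerated sign patterns).
#' @slot exhaustive TRUE when all 2^n sign patterns were enumerated.
#' @slot alpha significance level.
#' @slot seed seed used for the permutation draw.
#' @export
setClass("NBSResult",
  representation(
    clusters = "list", tCrit = "numeric", nullDistribution = "numeric",
    nPerm = "integer", exhaustive = "logical", alpha = "numeric",
    seed = "integer"
  )
)

setValidity("NBSResult", function(object) {
  msg <- character(0)
  for (cl in object@clusters) {
    if (!all(c("edges", "sign", "mass", "pFwer") %in% names(cl)))
      msg <- c(msg, "cluster entries need edges/sign/mass/pFwer")
    else if (cl$pFwer <= 0 || cl$pFwer > 1)
      msg <- c(msg, "pFwer must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Binary undirected network over the joint dyad node set
#'
#' @slot adjacency symmetric 0/1 matrix, zero diagonal; nodes are subject A's
#'   channels/ROIs followed by subject B's.
#' @slot nodeLabels character node labels carrying the subject tag.
#' @slot nodeSubject character "A"/"B" per node.
#' @slot nodeArea character area group per node (NA when ungrouped).
#' @export
setClass("BinaryNetwork",
  representation(
    adjacency = "matrix", nodeLabels = "character",
    nodeSubject = "character", nodeArea = "character"
  )
)

setValidity("BinaryNetwork", function(object) {
  msg <- character(0)
  a <- object@adjacency
  if (!isTRUE(all.equal(a, t(a)))) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
  n <- nrow(a)
  if (length(object@nodeLabels) != n || length(object@nodeSubject) != n ||
      length(object@nodeArea) != n)
    msg <- c(msg, "node annotation lengths must match node count")
  if (length(msg)) msg else TRUE
})

#' Graph-theoretic metrics of a binary network
#'
#' @slot degree integer per node.
#' @slot clustering per-node clustering coefficient in [0, 1].
#' @slot localEfficiency per-node local efficiency in [0, 1].
#' @slot transitivity scalar in [0, 1].
#' @slot globalEfficiency scalar in [0, 1].
#' @slot nodeLabels node labels, aligned with the per-node vectors.
#' @export
setClass("GraphMetrics",
  representation(
    degree = "numeric", clustering = "numeric", localEfficiency = "numeric",
    transitivity = "numeric", globalEfficiency = "numeric",
    nodeLabels = "character"
  )
)

setValidity("GraphMetrics", function(object) {
  msg <- character(0)
  if (object@globalEfficiency > 1 + 1e-12)
    msg <- c(msg, "global efficiency cannot exceed 1")
  if (any(object@clustering < -1e-12 | object@clustering > 1 + 1e-12))
    msg <- c(msg, "clustering coefficients must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
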