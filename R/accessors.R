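#' @include AllClasses.R
NULL

#' Accessors for dyadsync objects
#'
#' Small read-only accessors so downstream code never touches slots directly.
#'
#' @param x a dyadsync S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "DyadRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedBand", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "PhaseSeries", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "ROISeries", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("subjectData", function(x, role = c("A", "B"))
  standardGeneric("subjectData"))
#' @rdname accessors
#' @export
setMethod("subjectData", "DyadRecording", function(x, role = c("A", "B")) {
  role <- match.arg(role)
  if (role == "A") x@dataA else x@dataB
})

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "DyadRecording", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setMethod("eventTable", "DyadRecording", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("dyadId", function(x) standardGeneric("dyadId"))
#' @rdname accessors
#' @export
setMethod("dyadId", "DyadRecording", function(x) x@dyadId)

#' @rdname accessors
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))
#' @rdname accessors
#' @export
setMethod("bandName", "EpochedBand", function(x) x@band)
#' @rdname accessors
#' @export
setMethod("bandName", "PhaseSeries", function(x) x@band)
#' @rdname accessors
#' @export
setMethod("bandName", "InterbrainMatrix", function(x) x@band)

#' @rdname accessors
#' @export
setGeneric("phaseMatrix", function(x) standardGeneric("phaseMatrix"))
#' @rdname accessors
#' @export
setMethod("phaseMatrix", "PhaseSeries", function(x) x@phase)

#' @rdname accessors
#' @export
setGeneric("channelMask", function(x) standardGeneric("channelMask"))
#' @rdname accessors
#' @export
setMethod("channelMask", "PhaseSeries", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("syncValues", function(x) standardGeneric("syncValues"))
#' @rdname accessors
#' @export
setMethod("syncValues", "InterbrainMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("syncMetric", function(x) standardGeneric("syncMetric"))
#' @rdname accessors
#' @export
setMethod("syncMetric", "InterbrainMatrix", function(x) x@metric)

#' @rdname accessors
#' @export
setGeneric("componentCorrelations", function(x)
  standardGeneric("componentCorrelations"))
#' @rdname accessors
#' @export
setMethod("componentCorrelations", "CorrelatedComponents",
          function(x) x@correlations)

#' @rdname accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))
#' @rdname accessors
#' @export
setMethod("componentWeights", "CorrelatedComponents", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("sourceActivity", function(x) standardGeneric("sourceActivity"))
#' @rdname accessors
#' @export
setMethod("sourceActivity", "SourceEstimate", function(x) x@activity)
#' @rdname accessors
#' @export
setMethod("sourceActivity", "CortexFixture", function(x) x@sourceActivity)

#' @rdname accessors
#' @export
setGeneric("roiSeries", function(x) standardGeneric("roiSeries"))
#' @rdname accessors
#' @export
setMethod("roiSeries", "ROISeries", function(x) x@series)

#' @rdname accessors
#' @export
setGeneric("nbsClusters", function(x) standardGeneric("nbsClusters"))
#' @rdname accessors
#' @export
setMethod("nbsClusters", "NBSResult", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))
#' @rdname accessors
#' @export
setMethod("nullDistribution", "NBSResult", function(x) x@nullDistribution)

#' Significant clusters of an NBS result
#'
#' @param x an \code{NBSResult}.
#' @param alpha significance level; defaults to the level stored in the
#'   result.
#' @return list of clusters with \code{pFwer <= alpha}.
#' @export
significantClusters <- function(x, alpha = x@alpha) {
  stopifnot(is(x, "NBSResult"))
  Filter(function(cl) cl$pFwer <= alpha, x@clusters)
}

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "BinaryNetwork", function(x) x@adjacency)

setMethod("show", "DyadRecording", function(object) {
  cat(sprintf("DyadRecording '%s': %d channels x %d samples per subject @ %g Hz\n",
              object@dyadId, nrow(object@dataA), ncol(object@dataA), object@fs))
  if (nrow(object@events))
    cat("  events:", paste(sprintf("%s@%d", object@events$label,
                                   object@events$sample), collapse = ", "), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d ch @ %g Hz, %g s, band %s, ",
                     "%d coupled pair(s), kappa=%g, lag=%.3g rad\n"),
              object@nChannels, object@fs, object@duration, object@band,
              nrow(object@coupledPairs), object@kappa, object@lag))
})

setMethod("show", "InterbrainMatrix", function(object) {
  cat(sprintf("InterbrainMatrix [%s] %d x %d, band %s, condition '%s', dyad '%s'\n",
              object@metric, nrow(object@values), ncol(object@values),
              object@band, object@condition, object@dyadId))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  range [%.3f, %.3f], mean %.3f\n", min(v), max(v), mean(v)))
})

setMethod("show", "CorrelatedComponents", function(object) {
  k <- length(object@correlations)
  cat(sprintf("CorrelatedComponents: %d component(s), gamma=%g\n",
              k, object@regularization))
  cat("  top correlations:",
      paste(sprintf("%.3f", utils::head(object@correlations, 3)), collapse = ", "),
      sprintf(" (ISC top-3 = %.3f)\n", sum(utils::head(object@correlations, 3))))
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf("NBSResult: %d cluster(s), t_crit=%g, %d permutation(s)%s, alpha=%g\n",
              length(object@clusters), object@tCrit, object@nPerm,
              if (object@exhaustive) " (exhaustive)" else "", object@alpha))
  for (i in seq_along(object@clusters)) {
    cl <- object@clusters[[i]]
    cat(sprintf("  #%d: %d edge(s), sign %+d, mass %.2f, p_fwer %.4f%s\n",
                i, nrow(cl$edges), cl$sign, cl$mass, cl$pFwer,
                if (cl$pFwer <= object@alpha) " *" else ""))
  }
})

setMethod("show", "GraphMetrics", function(object) {
  cat(sprintf(paste0("GraphMetrics: %d nodes, mean degree %.2f, ",
                     "transitivity %.3f, E_glob %.3f\n"),
              length(object@degree), mean(object@degree),
              object@transitivity, object@globalEfficiency))
})
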