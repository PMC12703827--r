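#' Build a simulation configuration
#'
#' Constructs and validates the parameter set for the coupled-oscillator dyad
#' generator. Defaults mirror a typical dyadic hyperscanning acquisition:
#' 32 channels per subject, 500 Hz, 3-minute trials.
#'
#' @param nChannels channels per subject.
#' @param fs sampling rate, Hz.
#' @param duration trial length, seconds.
#' @param band oscillation band: "delta", "theta", "alpha" or "beta".
#' @param coupledPairs two-column matrix (or NULL) of (channel A, channel B)
#'   pairs carrying interbrain phase coupling.
#' @param kappa von Mises concentration of the phase jitter between coupled
#'   channels; 0 means independent, large values mean rigid locking.
#' @param lag mean phase difference of coupled pairs, radians, in [0, pi).
#'   A zero lag is legal but the phase lag index is blind to it by design.
#' @param noiseSd standard deviation of the pink-noise background, uV.
#' @param lineAmp amplitude of the 50 Hz line contaminant, uV.
#' @param seed integer random seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nChannels = 8, duration = 20,
#'                         coupledPairs = cbind(1, 1), kappa = 10)
#' @export
simulationConfig <- function(nChannels = 32L, fs = 500, duration = 180,
                             band = "alpha", coupledPairs = NULL,
                             kappa = 0, lag = pi / 4, noiseSd = 1,
                             lineAmp = 0.5, seed = 1L) {
  if (is.null(coupledPairs)) coupledPairs <- matrix(integer(0), ncol = 2)
  coupledPairs <- matrix(as.integer(coupledPairs), ncol = 2,
                         dimnames = NULL)
  new("SimulationConfig",
      nChannels = as.integer(nChannels), fs = fs, duration = duration,
      band = band, coupledPairs = coupledPairs, kappa = kappa, lag = lag,
      noiseSd = noiseSd, lineAmp = lineAmp, seed = as.integer(seed))
}

# one narrowband phase trajectory: the instantaneous frequency is an AR(1)
# process with ~0.3 s correlation time whose stationary spread covers the
# band, integrated to phase. Independent channels then accumulate phase
# differences quickly, so null PLI/PLV decay as expected with trial length.
.bandPhase <- function(nSamples, fs, band) {
  edges <- bandTable()[[band]]
  mid <- mean(edges); half <- diff(edges) / 2
  a <- exp(-1 / (0.3 * fs))
  z <- as.numeric(stats::filter(stats::rnorm(nSamples, 0, sqrt(1 - a^2)),
                                a, method = "recursive"))
  f <- mid + half * 0.9 * pmin(pmax(z, -1.5), 1.5) / 1.5
  cumsum(2 * pi * f / fs) + stats::runif(1, -pi, pi)
}

#' Simulate one dyad with known interbrain phase coupling
#'
#' Subject A's channels carry independent narrowband oscillations whose
#' instantaneous frequency wanders inside the configured band. For each
#' coupled channel pair, subject B's phase is A's phase plus the configured
#' lag plus per-sample von Mises jitter of concentration \code{kappa}; the
#' circular distribution of the planted phase difference is therefore exactly
#' von Mises(lag, kappa). All other channels are independent oscillations.
#' Pink background noise and a 50 Hz line sinusoid are added to every
#' channel.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dyadId identifier stored on the recording.
#' @param conditionLabel label of the single event mark placed at sample 0.
#' @return a \linkS4class{DyadRecording}.
#' @export
simulateDyad <- function(config, dyadId = "dyad01", conditionLabel = "trial") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (config@lag == 0 && config@kappa > 0 && nrow(config@coupledPairs) > 0)
    warning("lag = 0: coupling is planted but the phase lag index cannot see it")
  set.seed(config@seed)
  n <- as.integer(round(config@duration * config@fs))
  nc <- config@nChannels
  amp <- 10  # oscillation amplitude, uV
  t <- seq_len(n) / config@fs
  line <- config@lineAmp * sin(2 * pi * 50 * t)

  phasesA <- matrix(0, nc, n)
  for (ch in seq_len(nc)) phasesA[ch, ] <- .bandPhase(n, config@fs, config@band)
  dataA <- amp * sin(phasesA)

  dataB <- matrix(0, nc, n)
  coupledB <- rep(FALSE, nc)
  for (p in seq_len(nrow(config@coupledPairs))) {
    chA <- config@coupledPairs[p, 1]
    chB <- config@coupledPairs[p, 2]
    jitter <- rVonMises(n, mu = config@lag, kappa = config@kappa)
    dataB[chB, ] <- amp * sin(phasesA[chA, ] + jitter)
    coupledB[chB] <- TRUE
  }
  for (ch in which(!coupledB))
    dataB[ch, ] <- amp * sin(.bandPhase(n, config@fs, config@band))

  for (ch in seq_len(nc)) {
    dataA[ch, ] <- dataA[ch, ] + pinkNoise(n, config@noiseSd) + line
    dataB[ch, ] <- dataB[ch, ] + pinkNoise(n, config@noiseSd) + line
  }
  labels <- montageLabels(nc)
  rownames(dataA) <- rownames(dataB) <- labels
  new("DyadRecording",
      dataA = dataA, dataB = dataB, fs = config@fs, channelLabels = labels,
      events = data.frame(sample = 0L, label = conditionLabel,
                          stringsAsFactors = FALSE),
      dyadId = dyadId)
}

#' Simulate a two-condition dyad cohort
#'
#' Generates \code{nDyads} dyads, each recorded under an effect condition
#' ("F", coupling concentration \code{kappaEffect} on \code{effectPairs}) and
#' a null condition ("N", concentration \code{kappaNull} on the same pairs).
#' Per-dyad, per-condition child seeds are derived deterministically from the
#' master seed in \code{config}, so any single dyad can be regenerated in
#' isolation.
#'
#' @param nDyads number of dyads (>= 2).
#' @param effectPairs two-column matrix of coupled (channel A, channel B)
#'   pairs.
#' @param kappaEffect coupling concentration in the effect condition.
#' @param kappaNull coupling concentration in the null condition.
#' @param config base \linkS4class{SimulationConfig}; its \code{seed} acts as
#'   the master seed.
#' @return list of length \code{nDyads}; each element is a list with
#'   recordings \code{F} and \code{N}.
#' @export
simulateConditionSet <- function(nDyads, effectPairs, kappaEffect, kappaNull,
                                 config) {
  if (nDyads < 2) stop("nDyads must be >= 2")
  if (kappaEffect > 0 &&
      (is.null(effectPairs) || nrow(as.matrix(effectPairs)) == 0))
    stop("effectPairs must be non-empty when kappaEffect > 0")
  effectPairs <- matrix(as.integer(as.matrix(effectPairs)), ncol = 2)
  out <- vector("list", nDyads)
  for (d in seq_len(nDyads)) {
    cfgF <- simulationConfig(
      nChannels = config@nChannels, fs = config@fs, duration = config@duration,
      band = config@band, coupledPairs = effectPairs, kappa = kappaEffect,
      lag = config@lag, noiseSd = config@noiseSd, lineAmp = config@lineAmp,
      seed = childSeed(config@seed, d, 1L))
    cfgN <- simulationConfig(
      nChannels = config@nChannels, fs = config@fs, duration = config@duration,
      band = config@band, coupledPairs = effectPairs, kappa = kappaNull,
      lag = config@lag, noiseSd = config@noiseSd, lineAmp = config@lineAmp,
      seed = childSeed(config@seed, d, 2L))
    id <- sprintf("dyad%02d", d)
    out[[d]] <- list(F = simulateDyad(cfgF, id, "F"),
                     N = simulateDyad(cfgN, id, "N"))
  }
  names(out) <- vapply(out, function(x) x$F@dyadId, character(1))
  out
}

#' Simulate a toy forward model for the cortex branch
#'
#' Builds a lead-field gain matrix with a controlled condition number (random
#' orthogonal factors around a log-spaced singular spectrum, then projected
#' onto the average-reference sensor subspace), an atlas partitioning the
#' sources into 62 regions, and source activity with a chosen set of active
#' sources carrying narrowband oscillations.
#'
#' @param nChannels number of scalp channels (>= 8).
#' @param nSources number of cortical sources (>= 62).
#' @param seed integer seed.
#' @param activeSources integer indices of sources given nonzero activity
#'   (default: none; activity all zero).
#' @param duration seconds of source activity to generate.
#' @param fs sampling rate of the activity, Hz.
#' @param band band of the active-source oscillations.
#' @param conditionNumber ratio of largest to smallest nonzero singular value
#'   of the lead field.
#' @return a \linkS4class{CortexFixture}.
#' @export
simulateCortexFixture <- function(nChannels, nSources, seed = 1L,
                                  activeSources = integer(0), duration = 4,
                                  fs = 250, band = "alpha",
                                  conditionNumber = 50) {
  if (nSources < 62) stop("nSources must be >= 62 so every ROI is non-empty")
  if (nChannels < 8) stop("nChannels must be >= 8")
  set.seed(as.integer(seed))
  # random orthogonal factors via QR of Gaussian matrices; the singular
  # spectrum is log-spaced so the condition number is exactly as requested
  r <- min(nChannels, nSources)
  qu <- qr.Q(qr(matrix(stats::rnorm(nChannels * r), nChannels, r)))
  qv <- qr.Q(qr(matrix(stats::rnorm(nSources * r), nSources, r)))
  s <- exp(seq(0, -log(conditionNumber), length.out = r))
  A <- qu %*% (s * t(qv))
  # project rows onto the average-reference subspace (columns sum to zero)
  A <- A - matrix(colMeans(A), nChannels, nSources, byrow = TRUE)

  atlas <- as.integer(rep_len(seq_len(62L), nSources))
  n <- as.integer(round(duration * fs))
  X <- matrix(0, nSources, n)
  for (s0 in activeSources) X[s0, ] <- 10 * sin(.bandPhase(n, fs, band))
  atlasTab <- dktAtlasTable()
  new("CortexFixture",
      leadfield = A, sourceActivity = X, atlas = atlas,
      roiNames = atlasTab$roi, roiAreas = atlasTab$area, fs = fs)
}

#' Write a cortex fixture to a directory of TSV files
#'
#' Serializes the lead field and source activity as TSV matrices and the
#' atlas as a two-column (source_index, ROI_label) TSV.
#'
#' @param fixture a \linkS4class{CortexFixture}.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeCortexFixture <- function(fixture, dir) {
  stopifnot(is(fixture, "CortexFixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fixture@leadfield, file.path(dir, "leadfield.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(fixture@sourceActivity, file.path(dir, "source_activity.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(source_index = seq_along(fixture@atlas) - 1L,
               roi_label = fixture@roiNames[fixture@atlas]),
    file.path(dir, "atlas.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(as.character(fixture@fs), file.path(dir, "fs.txt"))
  invisible(dir)
}

#' Read a cortex fixture directory written by \code{writeCortexFixture}
#'
#' @param dir directory containing \code{leadfield.tsv},
#'   \code{source_activity.tsv}, \code{atlas.tsv} and \code{fs.txt}.
#' @return a \linkS4class{CortexFixture}.
#' @export
readCortexFixture <- function(dir) {
  A <- as.matrix(utils::read.table(file.path(dir, "leadfield.tsv"), sep = "\t"))
  X <- as.matrix(utils::read.table(file.path(dir, "source_activity.tsv"),
                                   sep = "\t"))
  dimnames(A) <- dimnames(X) <- NULL
  atlasTab <- dktAtlasTable()
  amap <- utils::read.table(file.path(dir, "atlas.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  atlas <- match(amap$roi_label, atlasTab$roi)
  fs <- as.numeric(readLines(file.path(dir, "fs.txt")))
  new("CortexFixture", leadfield = A, sourceActivity = X,
      atlas = as.integer(atlas), roiNames = atlasTab$roi,
      roiAreas = atlasTab$area, fs = fs)
}

#' Write a dyad cohort to EDF files plus a manifest
#'
#' One EDF per subject; a manifest TSV lists dyad id, condition, subject
#' files and the seed-bearing order so a cohort can be reloaded or shared.
#'
#' @param dyads list as returned by \code{\link{simulateConditionSet}} (or a
#'   list of single \linkS4class{DyadRecording}s).
#' @param dir output directory.
#' @return path of the manifest file, invisibly.
#' @export
writeDyadCohort <- function(dyads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(dyads)) {
    entry <- dyads[[nm]]
    recs <- if (is(entry, "DyadRecording")) list(trial = entry) else entry
    for (cond in names(recs)) {
      rec <- recs[[cond]]
      fA <- file.path(dir, sprintf("%s_%s_A.edf", nm, cond))
      fB <- file.path(dir, sprintf("%s_%s_B.edf", nm, cond))
      writeEDF(rec@dataA, rec@fs, rec@channelLabels, fA)
      writeEDF(rec@dataB, rec@fs, rec@channelLabels, fB)
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = nm, condition = cond,
        file_A = basename(fA), file_B = basename(fB),
        event_sample = rec@events$sample[1], event_label = rec@events$label[1],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dyad cohort from a manifest directory
#'
#' @param dir directory containing \code{manifest.tsv} and the EDF files it
#'   references.
#' @return nested list: dyad id -> condition -> \linkS4class{DyadRecording}.
#' @export
readDyadCohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    a <- readEDF(file.path(dir, row$file_A))
    b <- readEDF(file.path(dir, row$file_B))
    rec <- new("DyadRecording",
               dataA = a$data, dataB = b$data, fs = a$fs,
               channelLabels = a$labels,
               events = data.frame(sample = as.integer(row$event_sample),
                                   label = row$event_label,
                                   stringsAsFactors = FALSE),
               dyadId = row$dyad_id)
    out[[row$dyad_id]][[row$condition]] <- rec
  }
  out
}
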