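# Config-driven end-to-end orchestration: simulate a dyad cohort, compute
# the ISC condition contrast, build scalp PLI matrices, run the NBS
# contrast, run the toy cortex branch (sLORETA -> ROI PLV -> thresholded
# graph metrics), and write a JSON report.

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks on a YAML file or an equivalent list;
#' never touches heavy data.
#'
#' @param config path to a YAML file, or a list.
#' @return character vector of error messages; empty when the config is
#'   valid.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "isc", "nbs", "cortex")
  known <- c("simulate", "isc", "nbs", "cortex")
  chk(all(stages %in% known),
      sprintf("unknown stage(s): %s", paste(setdiff(stages, known), collapse = ", ")))
  if ("nbs" %in% stages && !"simulate" %in% stages && is.null(config$input_dir))
    errs <- c(errs, "nbs requires connectivity input: add the simulate stage or input_dir")
  bands <- config$bands
  if (is.null(bands)) bands <- "alpha"
  chk(all(bands %in% names(bandTable())),
      sprintf("unknown band(s): %s (the pipeline knows delta/theta/alpha/beta)",
              paste(setdiff(bands, names(bandTable())), collapse = ", ")))
  sim <- config$simulation
  stochastic <- any(c("simulate", "nbs", "cortex") %in% stages)
  chk(!stochastic || !is.null(config$seed),
      "seed is mandatory when any stochastic stage runs")
  if (!is.null(sim)) {
    if (!is.null(sim$kappa_effect) && sim$kappa_effect > 0)
      chk(length(sim$effect_pairs) > 0,
          "effect_pairs must be non-empty when kappa_effect > 0")
    if (!is.null(sim$n_dyads)) chk(sim$n_dyads >= 2, "n_dyads must be >= 2")
    if (!is.null(sim$band))
      chk(sim$band %in% names(bandTable()),
          sprintf("unknown simulation band '%s'", sim$band))
  }
  nbs <- config$nbs
  if (!is.null(nbs)) {
    if (!is.null(nbs$alpha))
      chk(nbs$alpha > 0 && nbs$alpha < 1, "nbs alpha must lie in (0, 1)")
    if (!is.null(nbs$n_perm)) chk(nbs$n_perm >= 1, "n_perm must be >= 1")
  }
  thr <- config$threshold
  if (!is.null(thr$p)) chk(thr$p > 0 && thr$p <= 1, "threshold p must lie in (0, 1]")
  if (!is.null(config$input_dir))
    chk(dir.exists(config$input_dir),
        sprintf("input_dir '%s' does not exist", config$input_dir))
  errs
}

.asPairs <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, function(p) as.integer(unlist(p))))
}

#' Run the full pipeline from a configuration
#'
#' Deterministic given the config seed: simulates the cohort, computes the
#' ISC table and paired contrast per band, scalp interbrain PLI matrices,
#' the NBS contrast between the effect and null conditions, the toy cortex
#' branch, and graph metrics of the thresholded cortex network. Writes a
#' JSON report plus per-stage TSV outputs under \code{output_dir} and
#' returns the report invisibly.
#'
#' @param config path to a YAML config or an equivalent list.
#' @param quiet suppress per-stage progress messages.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validateConfig(config)
  if (length(errs))
    stop("invalid config:\n", paste("  -", errs, collapse = "\n"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "isc", "nbs", "cortex")
  bands <- config$bands; if (is.null(bands)) bands <- "alpha"
  outDir <- config$output_dir
  if (is.null(outDir)) outDir <- tempfile("dyadsync_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config, stages = list())
  logPath <- file.path(outDir, "run.log")
  cat(sprintf("[%s] pipeline start\n", format(Sys.time())), file = logPath)
  t0 <- proc.time()[["elapsed"]]
  mark <- function(stage, t1) cat(sprintf("[%s] stage %s done in %.2f s\n",
    format(Sys.time()), stage, proc.time()[["elapsed"]] - t1),
    file = logPath, append = TRUE)

  sim <- config$simulation
  cohort <- NULL
  if ("simulate" %in% stages) {
    say("stage simulate: %d dyads, %g s @ %g Hz", sim$n_dyads, sim$duration, sim$fs)
    base <- simulationConfig(
      nChannels = sim$n_channels, fs = sim$fs, duration = sim$duration,
      band = sim$band, kappa = 0,
      lag = if (is.null(sim$lag)) pi / 4 else sim$lag,
      noiseSd = if (is.null(sim$noise_sd)) 1 else sim$noise_sd,
      lineAmp = if (is.null(sim$line_amp)) 0.5 else sim$line_amp,
      seed = config$seed)
    cohort <- simulateConditionSet(sim$n_dyads, .asPairs(sim$effect_pairs),
                                   sim$kappa_effect, sim$kappa_null, base)
    report$stages$simulate <- list(n_dyads = sim$n_dyads)
    mark("simulate", t0)
  } else if (!is.null(config$input_dir)) {
    cohort <- readDyadCohort(config$input_dir)
  }

  if ("isc" %in% stages) {
    t1 <- proc.time()[["elapsed"]]
    say("stage isc: bands %s", paste(bands, collapse = ","))
    isc <- iscConditionTable(cohort, bands = bands, contrast = c("F", "N"))
    utils::write.table(isc$table, file.path(outDir, "isc_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meansList <- lapply(seq_len(nrow(isc$means)),
                        function(i) as.list(isc$means[i, ]))
    names(meansList) <- rownames(isc$means)
    report$stages$isc <- list(means = meansList, tests = isc$tests)
    mark("isc", t1)
  }

  matsF <- matsN <- NULL
  if (any(c("nbs") %in% stages)) {
    t1 <- proc.time()[["elapsed"]]
    b <- bands[1]
    say("stage conn+nbs: scalp PLI matrices, band %s", b)
    mk <- function(rec, cond) {
      ep <- preprocessDyad(rec, b, conditionLabel = cond)
      pa <- instantaneousPhase(ep$A); pb <- instantaneousPhase(ep$B)
      interbrainMatrix(pa, pb, condition = cond, dyadIdent = rec@dyadId)
    }
    matsF <- lapply(cohort, function(d) mk(d$F, "F"))
    matsN <- lapply(cohort, function(d) mk(d$N, "N"))
    nbsCfg <- config$nbs
    res <- nbsTest(matsF, matsN,
                   nPerm = if (is.null(nbsCfg$n_perm)) 5000 else nbsCfg$n_perm,
                   tCrit = if (is.null(nbsCfg$t_crit)) 1.96 else nbsCfg$t_crit,
                   alpha = if (is.null(nbsCfg$alpha)) 0.05 else nbsCfg$alpha,
                   seed = config$seed, contrast = c("F", "N"))
    tmap <- suppressWarnings(edgeT(matsF, matsN, c("F", "N")))
    writeNbsEdges(res, tmap, file.path(outDir, "nbs_edges.tsv"),
                  rowLabels = matsF[[1]]@rowLabels,
                  colLabels = matsF[[1]]@colLabels)
    report$stages$nbs <- list(
      n_clusters = length(res@clusters),
      significant = length(significantClusters(res)),
      clusters = lapply(res@clusters, function(cl)
        list(n_edges = nrow(cl$edges), sign = cl$sign,
             mass = cl$mass, p_fwer = cl$pFwer)))
    mark("nbs", t1)
  }

  if ("cortex" %in% stages) {
    t1 <- proc.time()[["elapsed"]]
    cx <- config$cortex
    nch <- if (is.null(cx$n_channels)) 64L else cx$n_channels
    nsrc <- if (is.null(cx$n_sources)) 62L else cx$n_sources
    dur <- if (is.null(cx$duration)) 8 else cx$duration
    say("stage cortex: %d channels, %d sources", nch, nsrc)
    srcA <- if (is.null(cx$source_a)) 5L else as.integer(cx$source_a)
    srcB <- if (is.null(cx$source_b)) 11L else as.integer(cx$source_b)
    fix <- simulateCortexFixture(nch, nsrc, seed = childSeed(config$seed, 99L),
                                 activeSources = seq_len(nsrc), duration = dur)
    fixB <- simulateCortexFixture(nch, nsrc, seed = childSeed(config$seed, 98L),
                                  activeSources = seq_len(nsrc), duration = dur)
    Xa <- fix@sourceActivity
    Xb <- fixB@sourceActivity
    Xb[srcB, ] <- Xa[srcA, ]          # shared oscillation: planted ROI coupling
    ya <- fix@leadfield %*% Xa
    yb <- fix@leadfield %*% Xb
    estA <- sloretaInverse(ya, fix@leadfield, lambda = 0)
    estB <- sloretaInverse(yb, fix@leadfield, lambda = 0)
    roiA <- roiReduce(estA, fix)
    roiB <- roiReduce(estB, fixB)
    cmat <- cortexInterbrain(roiA, roiB, band = bands[1], condition = "F")
    thr <- config$threshold
    pKeep <- if (is.null(thr$p)) 0.2 else thr$p
    thrMat <- thresholdMatrix(cmat, "proportional", p = pKeep)
    net <- binarize(thrMat, areas = fix@roiAreas)
    gm <- graphMetrics(net)
    agg <- areaAggregate(gm, net)
    utils::write.table(agg, file.path(outDir, "cortex_area_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    peak <- which(cmat@values == max(cmat@values), arr.ind = TRUE)[1, ]
    report$stages$cortex <- list(
      planted_roi_a = fix@roiNames[fix@atlas[srcA]],
      planted_roi_b = fix@roiNames[fix@atlas[srcB]],
      peak_roi_a = cmat@rowLabels[peak[1]],
      peak_roi_b = cmat@colLabels[peak[2]],
      peak_plv = max(cmat@values),
      mean_degree = mean(gm@degree),
      transitivity = gm@transitivity,
      global_efficiency = gm@globalEfficiency)
    mark("cortex", t1)
  }

  cat(sprintf("[%s] pipeline done in %.2f s\n", format(Sys.time()),
              proc.time()[["elapsed"]] - t0), file = logPath, append = TRUE)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  say("report written to %s", file.path(outDir, "report.json"))
  invisible(report)
}
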