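# Synthetic dyad generator: ground-truth coupling, determinism, config
# validation, cortex fixtures and EDF round trips.

test_that("config validation rejects inconsistent parameters", {
  expect_error(simulationConfig(band = "gamma"), "unknown band")
  expect_error(simulationConfig(kappa = -1), "kappa")
  expect_error(simulationConfig(nChannels = 4, coupledPairs = cbind(5L, 1L)),
               "out of channel range")
  expect_error(simulationConfig(nChannels = 4,
                                coupledPairs = rbind(c(1, 2), c(1, 2))),
               "duplicate")
  expect_error(simulationConfig(nChannels = 4,
                                coupledPairs = rbind(c(1, 2), c(3, 2))),
               "at most one")
  # < 10 cycles of the band low edge
  expect_error(simulationConfig(band = "delta", duration = 5), "too short")
  expect_error(simulationConfig(lag = pi), "lag")
})

test_that("same seed gives a bit-identical recording", {
  cfg <- quickConfig(coupledPairs = cbind(1L, 1L), kappa = 5, duration = 12)
  r1 <- simulateDyad(cfg)
  r2 <- simulateDyad(cfg)
  expect_identical(subjectData(r1, "A"), subjectData(r2, "A"))
  expect_identical(subjectData(r1, "B"), subjectData(r2, "B"))
})

test_that("rigid nonzero-lag locking yields PLI near 1 through the pipeline", {
  cfg <- quickConfig(nChannels = 16L, duration = 30,
                     coupledPairs = cbind(1L, 1L), kappa = 1e6, lag = pi / 4,
                     seed = 7L)
  rec <- simulateDyad(cfg)
  expect_gt(pipelinePli(rec), 0.95)
})

test_that("uncoupled dyads give near-zero PLI at trial length", {
  cfg <- quickConfig(duration = 30, kappa = 0, seed = 5L)
  rec <- simulateDyad(cfg)
  ep <- preprocessDyad(rec, "alpha")
  m <- syncValues(interbrainMatrix(instantaneousPhase(ep$A),
                                   instantaneousPhase(ep$B)))
  # null PLI fluctuations shrink with sample count; a generous cap
  expect_lt(max(m), 0.35)
  expect_lt(mean(m), 0.15)
})

test_that("planted circular phase-difference distribution matches lag and kappa", {
  kappa <- 4; lag <- pi / 3
  n <- 20000
  set.seed(9)
  jitter <- dyadsync:::rVonMises(n, mu = lag, kappa = kappa)
  expect_lt(abs(dyadsync:::circularMean(jitter) - lag), 0.03)
  # resultant length estimates the concentration: R = I1(k)/I0(k)
  R <- Mod(mean(exp(1i * jitter)))
  expected <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_lt(abs(R - expected), 0.02)
})

test_that("empirical PLI increases with coupling concentration", {
  kappas <- c(0, 2, 8, 32)
  vals <- vapply(kappas, function(k) {
    cfg <- quickConfig(duration = 20, coupledPairs = cbind(1L, 1L),
                       kappa = k, seed = 3L)
    pipelinePli(simulateDyad(cfg))
  }, numeric(1))
  expect_true(all(diff(vals) > -0.02))   # monotone up to simulation noise
  expect_gt(vals[4], vals[1] + 0.5)
})

test_that("condition sets pair an effect and a null recording per dyad", {
  cfg <- quickConfig(duration = 12)
  expect_error(simulateConditionSet(1, cbind(1L, 1L), 5, 0, cfg), ">= 2")
  expect_error(simulateConditionSet(4, matrix(integer(0), ncol = 2), 5, 0, cfg),
               "non-empty")
  set <- simulateConditionSet(3, cbind(1L, 1L), 5, 0, cfg)
  expect_length(set, 3)
  expect_named(set[[1]], c("F", "N"))
  # per-dyad child seeds: regenerating dyad 2 alone reproduces it
  cfg2 <- quickConfig(duration = 12, coupledPairs = cbind(1L, 1L), kappa = 5,
                      seed = dyadsync:::childSeed(cfg@seed, 2L, 1L))
  again <- simulateDyad(cfg2, "dyad02", "F")
  expect_identical(subjectData(set[[2]]$F, "A"), subjectData(again, "A"))
})

test_that("cortex fixture construction honors its contracts", {
  expect_error(simulateCortexFixture(16, 50), ">= 62")
  expect_error(simulateCortexFixture(4, 70), ">= 8")
  fix <- simulateCortexFixture(16, 124, seed = 2)
  expect_equal(length(unique(fix@atlas)), 62)
  expect_true(all(abs(colSums(fix@leadfield)) < 1e-8))
  # all-zero activity maps to exactly zero scalp data
  expect_equal(max(abs(fix@leadfield %*% sourceActivity(fix))), 0)
  # single active source: Y is that column scaled by the activity
  fix1 <- simulateCortexFixture(16, 124, seed = 2, activeSources = 7L,
                                duration = 2)
  y <- fix1@leadfield %*% sourceActivity(fix1)
  expect_equal(y, fix1@leadfield[, 7, drop = FALSE] %*%
                   sourceActivity(fix1)[7, , drop = FALSE])
})

test_that("cortex fixture survives a TSV round trip", {
  fix <- simulateCortexFixture(12, 70, seed = 3, activeSources = 5L,
                               duration = 1)
  dir <- tempfile("fixture_")
  writeCortexFixture(fix, dir)
  back <- readCortexFixture(dir)
  expect_equal(back@leadfield, fix@leadfield, tolerance = 1e-6)
  expect_equal(back@atlas, fix@atlas)
  expect_equal(back@fs, fix@fs)
})

test_that("EDF files round-trip dyad recordings within quantization error", {
  cfg <- quickConfig(nChannels = 4L, duration = 12, seed = 8L)
  rec <- simulateDyad(cfg)
  dir <- tempfile("cohort_")
  writeDyadCohort(list(dyad01 = rec), dir)
  back <- readDyadCohort(dir)
  r2 <- back$dyad01$trial
  expect_equal(samplingRate(r2), samplingRate(rec))
  expect_equal(channelLabels(r2), channelLabels(rec))
  scale <- max(abs(subjectData(rec, "A")))
  expect_lt(max(abs(subjectData(r2, "A") - subjectData(rec, "A"))),
            scale / 3e4)
  expect_lt(max(abs(subjectData(r2, "B") - subjectData(rec, "B"))),
            scale / 3e4)
  expect_equal(eventTable(r2)$label, "trial")
})
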