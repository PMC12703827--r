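# Preprocessing chain: downsampling, notch, average reference, band-pass,
# trial extraction, and the phase-preservation contract of the full chain.

fftPeakAmp <- function(x, fs, f0) {
  n <- length(x)
  X <- abs(fft(x)) / n * 2
  freqs <- (seq_len(n) - 1) * fs / n
  max(X[abs(freqs - f0) < 0.5])
}

test_that("downsampling halves the rate, keeps in-band tones, kills aliases", {
  fs <- 500
  t <- seq_len(4 * fs) / fs
  const <- matrix(1, 1, length(t))
  expect_equal(as.numeric(downsample(const, fs, 250)),
               rep(1, length(t) / 2), tolerance = 1e-6)
  tone10 <- matrix(sin(2 * pi * 10 * t), 1)
  y <- downsample(tone10, fs, 250)
  expect_equal(ncol(y), length(t) / 2)
  expect_equal(fftPeakAmp(as.numeric(y), 250, 10), 1, tolerance = 0.01)
  # 200 Hz aliases to 50 Hz at 250 Hz: must be suppressed >= 40 dB
  tone200 <- matrix(sin(2 * pi * 200 * t), 1)
  y2 <- downsample(tone200, fs, 250)
  expect_lt(fftPeakAmp(as.numeric(y2), 250, 50), 0.01)
  expect_error(downsample(tone10, 500, 600), "exceed")
  expect_error(downsample(tone10, 500, 300), "integer multiple")
})

test_that("notch removes 50 Hz and leaves neighbors untouched", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  mid <- 500:2000
  line <- sin(2 * pi * 50 * t)
  resid <- notchFilter(line, fs)
  expect_lt(sqrt(mean(resid[mid]^2)) / sqrt(mean(line[mid]^2)), 0.03)
  keep <- sin(2 * pi * 10 * t)
  out <- notchFilter(keep, fs)
  expect_lt(abs(sqrt(mean(out[mid]^2)) / sqrt(mean(keep[mid]^2)) - 1), 0.01)
  expect_equal(notchFilter(rep(0, 1000), fs), rep(0, 1000))
  expect_error(notchFilter(keep, fs = 90), "twice")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  x <- matrix(rnorm(5 * 100), 5)
  r <- averageReference(x)
  expect_lt(max(abs(colMeans(r))), 1e-12)
  expect_equal(averageReference(r), r)
  ab <- rbind(a = c(1, 2, 3), b = c(5, 4, 3))
  expect_equal(unname(averageReference(ab)),
               rbind((ab[1, ] - ab[2, ]) / 2, (ab[2, ] - ab[1, ]) / 2))
  expect_error(averageReference(matrix(1, 1, 10)), "2 channels")
})

test_that("band-pass is zero-phase and selective", {
  fs <- 250
  t <- seq_len(20 * fs) / fs
  inband <- sin(2 * pi * 10 * t)
  y <- bandpassFilter(inband, "alpha", fs)
  mid <- 1000:4000
  expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
  # zero-phase: mid-signal cross-correlation peaks at zero lag
  cc <- ccf(y[mid], inband[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  outband <- sin(2 * pi * 2 * t)
  y2 <- bandpassFilter(outband, "alpha", fs)
  expect_lt(sqrt(mean(y2[mid]^2)) / sqrt(mean(outband[mid]^2)), 0.1)
  expect_equal(bandpassFilter(rep(0, 1000), "alpha", fs), rep(0, 1000))
  expect_error(bandpassFilter(inband, "gamma", fs), "unknown band")
})

test_that("trial extraction cuts both subjects at identical samples", {
  cfg <- quickConfig(nChannels = 4L, duration = 12, seed = 2L)
  rec <- simulateDyad(cfg, conditionLabel = "F2F")
  seg <- extractTrials(rec, "F2F", trialLength = 10)
  expect_equal(ncol(seg$A), 10 * 500)
  expect_equal(ncol(seg$B), 10 * 500)
  expect_equal(seg$A, subjectData(rec, "A")[, 1:5000])
  expect_error(extractTrials(rec, "missing"), "no event")
  expect_error(extractTrials(rec, "F2F", trialLength = 100), "overruns")
})

test_that("duplicate event labels use the earliest with a warning", {
  cfg <- quickConfig(nChannels = 2L, duration = 12, seed = 3L)
  rec <- simulateDyad(cfg, conditionLabel = "x")
  rec@events <- data.frame(sample = c(1000L, 0L), label = c("x", "x"))
  expect_warning(seg <- extractTrials(rec, "x", trialLength = 2), "earliest")
  expect_equal(seg$A, subjectData(rec, "A")[, 1:1000])
})

test_that("notch and average reference commute", {
  x <- matrix(rnorm(4 * 2000), 4)
  a <- averageReference(notchFilter(x, 250))
  b <- notchFilter(averageReference(x), 250)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("the full chain preserves the planted phase relation", {
  cfg <- quickConfig(nChannels = 16L, duration = 30,
                     coupledPairs = cbind(1L, 1L), kappa = 1e6, lag = pi / 4,
                     seed = 11L)
  rec <- simulateDyad(cfg)
  # clean truth: rigid lag pi/4 means PLI exactly 1
  expect_lt(abs(pipelinePli(rec) - 1), 0.05)
})

test_that("preprocessDyad emits valid average-referenced band epochs", {
  cfg <- quickConfig(nChannels = 6L, duration = 12, seed = 4L)
  rec <- simulateDyad(cfg)
  ep <- preprocessDyad(rec, "theta")
  expect_s4_class(ep$A, "EpochedBand")
  expect_equal(samplingRate(ep$A), 250)
  expect_equal(bandName(ep$A), "theta")
  expect_identical(ep$A@subjectRole, "A")
  expect_identical(ep$B@subjectRole, "B")
})
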