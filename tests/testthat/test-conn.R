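# Phase extraction and the PLI/PLV synchronization metrics.

test_that("analytic phase of a pure tone is a linear ramp", {
  fs <- 250
  t <- seq_len(8 * fs) / fs
  x <- matrix(cos(2 * pi * 10 * t), 1)
  ps <- instantaneousPhase(x, fs = fs)
  ph <- phaseMatrix(ps)[1, ]
  mid <- 200:1200
  slopes <- diff(dyadsync:::wrapPhase(ph[mid]))
  slopes <- slopes[abs(slopes) < pi]     # unwrap point jumps
  expect_equal(median(slopes), 2 * pi * 10 / fs, tolerance = 1e-4)
})

test_that("sin and cos of the same tone are in quadrature", {
  fs <- 250
  t <- seq_len(8 * fs) / fs
  x <- rbind(sin(2 * pi * 8 * t), cos(2 * pi * 8 * t))
  ps <- instantaneousPhase(x, fs = fs)
  d <- dyadsync:::wrapPhase(phaseMatrix(ps)[2, ] - phaseMatrix(ps)[1, ])
  expect_equal(median(d), pi / 2, tolerance = 1e-3)
})

test_that("all-zero channels are masked instead of propagating NaN", {
  fs <- 250
  x <- rbind(sin(2 * pi * 10 * seq_len(4 * fs) / fs), 0)
  ps <- instantaneousPhase(x, fs = fs)
  expect_identical(channelMask(ps), c(FALSE, TRUE))
  m <- interbrainMatrix(ps, ps, metric = "pli")
  expect_true(all(is.na(syncValues(m)[2, ])))
  expect_true(all(is.na(syncValues(m)[, 2])))
  expect_false(anyNA(syncValues(m)[1, 1]))
})

test_that("PLI matches its defining formula on constructed phase differences", {
  base <- runif(4, -pi, pi)
  # constant nonzero lag: every sign is +1
  expect_equal(pli(base + pi / 4, base), 1)
  # the worked four-point example: signs (+1, +1, -1, +1)
  d <- c(pi / 4, pi / 6, -pi / 3, pi / 2)
  expect_equal(pli(d, rep(0, 4)), 0.5)
  # identical signals: sign(0) = 0 everywhere, PLI blind to zero lag
  expect_equal(pli(base, base), 0)
  # symmetry
  a <- runif(50, -pi, pi); b <- runif(50, -pi, pi)
  expect_equal(pli(a, b), pli(b, a))
  expect_error(pli(a, b[1:10]), "mismatch")
})

test_that("PLV matches its defining formula", {
  base <- runif(6, -pi, pi)
  expect_equal(plv(base, base), 1)             # zero lag still locks
  expect_equal(plv(base + 1.1, base), 1)       # any constant lag
  # three symmetric phasors cancel exactly
  expect_equal(plv(c(0, 2 * pi / 3, 4 * pi / 3), rep(0, 3)), 0,
               tolerance = 1e-12)
  a <- runif(50, -pi, pi); b <- runif(50, -pi, pi)
  expect_equal(plv(a, b), plv(b, a))
  expect_error(plv(a, b[1:10]), "mismatch")
})

test_that("null PLV at trial length stays below 0.02", {
  set.seed(21)
  T <- 45000
  # null PLV concentrates around sqrt(pi / (4 T)) ~ 0.0042 at this length
  vals <- replicate(20, plv(runif(T, -pi, pi), runif(T, -pi, pi)))
  expect_lt(max(vals), 0.02)
})

test_that("adding a common phase constant changes neither PLI nor PLV", {
  a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
  expect_equal(pli(a + 0.7, b + 0.7), pli(a, b))
  expect_equal(plv(a + 0.7, b + 0.7), plv(a, b))
})

test_that("PLI is zero for phase differences symmetric about zero", {
  d <- c(0.3, -0.3, 1.2, -1.2, 0.01, -0.01)
  expect_equal(pli(d, rep(0, 6)), 0)
})

test_that("the matrix op equals the scalar op entrywise", {
  set.seed(4)
  fs <- 250
  mkPhase <- function(role) {
    ph <- matrix(runif(2 * 100, -pi, pi), 2)
    new("PhaseSeries", phase = ph, fs = fs, band = "alpha",
        subjectRole = role, sourceKind = "scalp", mask = c(FALSE, FALSE))
  }
  pa <- mkPhase("A"); pb <- mkPhase("B")
  m <- syncValues(interbrainMatrix(pa, pb, metric = "pli"))
  for (i in 1:2) for (j in 1:2)
    expect_equal(m[i, j], pli(phaseMatrix(pa)[i, ], phaseMatrix(pb)[j, ]))
  m2 <- syncValues(interbrainMatrix(pa, pb, metric = "plv", force = TRUE))
  for (i in 1:2) for (j in 1:2)
    expect_equal(m2[i, j], plv(phaseMatrix(pa)[i, ], phaseMatrix(pb)[j, ]))
  # non-default metric for scalp data requires the explicit override
  expect_error(interbrainMatrix(pa, pb, metric = "plv"), "force")
})

test_that("thresholding keeps the right entries", {
  set.seed(5)
  v <- matrix(runif(62 * 62), 62)
  m <- new("InterbrainMatrix", values = v, metric = "plv",
           rowLabels = sprintf("r%02d", 1:62), colLabels = sprintf("c%02d", 1:62),
           band = "alpha", condition = "", dyadId = "")
  expect_equal(syncValues(thresholdMatrix(m, "proportional", p = 1)), v)
  thr <- thresholdMatrix(m, "proportional", p = 0.1)
  expect_equal(sum(syncValues(thr) > 0), ceiling(0.1 * 62 * 62))  # 385
  v2 <- v; v2[5, 7] <- 1
  m2 <- initialize(m, values = v2)
  ab <- thresholdMatrix(m2, "absolute", tau = 1.0)
  expect_equal(sum(syncValues(ab) >= 1), 1)
  expect_equal(which(syncValues(ab) == 1, arr.ind = TRUE)[1, ],
               c(row = 5, col = 7))
  expect_error(thresholdMatrix(m, "proportional", p = 0), "0, 1")
})
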