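# Correlated component analysis and the top-3 ISC score.

# independent oracle: dense generalized eigensolve via explicit inversion,
# a different route than the symmetric B^{-1/2} transform inside corrcaFit
oracleCorrelations <- function(xA, xB, gamma = 0) {
  nt <- ncol(xA)
  xA <- xA - rowMeans(xA); xB <- xB - rowMeans(xB)
  Raa <- tcrossprod(xA) / (nt - 1); Rbb <- tcrossprod(xB) / (nt - 1)
  Rab <- tcrossprod(xA, xB) / (nt - 1)
  P <- Raa + Rbb
  B <- P + gamma * mean(diag(P)) * diag(nrow(P))
  ev <- eigen(solve(B) %*% (Rab + t(Rab)))
  sort(Re(ev$values), decreasing = TRUE)
}

test_that("identical subjects give all component correlations equal to 1", {
  set.seed(1)
  x <- matrix(rnorm(6 * 400), 6)
  cc <- corrcaFit(x, x, shrinkage = 0)
  expect_equal(componentCorrelations(cc), rep(1, 6), tolerance = 1e-8)
  expect_equal(iscScore(cc), 3, tolerance = 1e-8)
})

test_that("correlations match a dense generalized-eigensolver oracle", {
  set.seed(2)
  for (nc in c(4, 6, 8)) {
    xA <- matrix(rnorm(nc * 200), nc)
    xB <- matrix(rnorm(nc * 200), nc)
    got <- componentCorrelations(corrcaFit(xA, xB, shrinkage = 0))
    expect_equal(got, oracleCorrelations(xA, xB), tolerance = 1e-8)
  }
})

test_that("a shared invertible mixing leaves the correlations unchanged", {
  set.seed(3)
  xA <- matrix(rnorm(8 * 300), 8)
  xB <- matrix(rnorm(8 * 300), 8)
  M <- matrix(rnorm(64), 8)
  base <- componentCorrelations(corrcaFit(xA, xB, shrinkage = 0))
  mixed <- componentCorrelations(corrcaFit(M %*% xA, M %*% xB, shrinkage = 0))
  expect_equal(mixed, base, tolerance = 1e-8)
})

test_that("independent noise stays below a circular-shift surrogate null", {
  set.seed(4)
  xA <- matrix(rnorm(4 * 3000), 4)
  xB <- matrix(rnorm(4 * 3000), 4)
  rho1 <- componentCorrelations(corrcaFit(xA, xB, shrinkage = 0))[1]
  nulls <- vapply(1:40, function(i) {
    s <- sample(500:2500, 1)
    xBs <- xB[, c((s + 1):3000, 1:s)]
    componentCorrelations(corrcaFit(xA, xBs, shrinkage = 0))[1]
  }, numeric(1))
  expect_lt(rho1, quantile(nulls, 0.95) + 0.05)
  expect_lt(abs(iscScore(corrcaFit(xA, xB, shrinkage = 0))), 0.3)
})

test_that("rank-deficient data demands shrinkage", {
  set.seed(5)
  x <- averageReference(matrix(rnorm(6 * 300), 6))
  y <- averageReference(matrix(rnorm(6 * 300), 6))
  expect_error(corrcaFit(x, y, shrinkage = 0), "shrinkage")
  cc <- corrcaFit(x, y, shrinkage = 0.05)
  expect_true(all(abs(componentCorrelations(cc)) <= 1 + 1e-9))
})

test_that("the ISC score enforces its contract", {
  expect_equal(iscScore(c(1, 1, 1, 0)), 3)
  expect_equal(iscScore(c(0.4, 0.2, 0.0)), 0.6)
  expect_error(iscScore(c(0.5, 0.3)), "3 components")
  expect_error(iscScore(c(0.5, 0.3, 0.1, 0.9)), "descending")
})

test_that("ISC recovery grows with the planted common-signal level", {
  set.seed(6)
  nt <- 800
  snrGrid <- c(0.2, 1, 4)
  scores <- vapply(snrGrid, function(snr) {
    mean(replicate(10, {
      shared <- matrix(rnorm(3 * nt), 3)
      mix <- matrix(rnorm(5 * 3), 5, 3)
      xA <- snr * (mix %*% shared) + matrix(rnorm(5 * nt), 5)
      xB <- snr * (mix %*% shared) + matrix(rnorm(5 * nt), 5)
      iscScore(corrcaFit(xA, xB, shrinkage = 0.01))
    }))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("the condition table pairs dyads and runs the paired contrast", {
  cfg <- quickConfig(nChannels = 6L, duration = 12)
  set <- simulateConditionSet(3, cbind(1L, 1L), 8, 0, cfg)
  res <- iscConditionTable(set, bands = "alpha", contrast = c("F", "N"))
  expect_equal(nrow(res$table), 6)       # 3 dyads x 2 conditions x 1 band
  expect_named(res$tests, "alpha")
  expect_true(is.finite(res$tests$alpha$p))
  expect_equal(res$tests$alpha$df, 2)
  # degenerate all-equal case: t = 0, p = 1 by convention
  same <- set
  for (i in 1:3) {
    r <- same[[i]]$F
    r@events$label <- "N"
    same[[i]]$N <- r
  }
  res2 <- iscConditionTable(same, bands = "alpha", contrast = c("F", "N"))
  expect_equal(res2$tests$alpha$t, 0)
  expect_equal(res2$tests$alpha$p, 1)
})

test_that("a single dyad yields a table but no paired test", {
  cfg <- quickConfig(nChannels = 6L, duration = 12)
  set <- simulateConditionSet(2, cbind(1L, 1L), 8, 0, cfg)[1]
  expect_error(iscConditionTable(set, bands = "alpha", contrast = c("F", "N")),
               "at least 2 dyads")
  res <- iscConditionTable(set, bands = "alpha", contrast = NULL)
  expect_equal(nrow(res$table), 2)
})
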