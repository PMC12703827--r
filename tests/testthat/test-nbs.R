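# Network-based statistic: edgewise paired t, signed clustering, sign-flip
# permutation null, FWER-corrected inference.

test_that("edgewise t matches the textbook paired formula", {
  d <- c(0.2, 0.3, 0.1, 0.4, 0.25)
  c2 <- lapply(seq_along(d), function(i) matrix(0.5, 1, 1))
  c1 <- lapply(seq_along(d), function(i) matrix(0.5 + d[i], 1, 1))
  tm <- edgeT(c1, c2)
  oracle <- mean(d) * sqrt(length(d)) / sd(d)
  expect_equal(tm@t[1, 1], oracle, tolerance = 1e-10)
  expect_equal(tm@df, 4)
})

test_that("degenerate edges are handled, not infinite", {
  c1 <- lapply(1:4, function(i) matrix(c(0.9, 0.5), 1, 2))
  c2 <- lapply(1:4, function(i) matrix(c(0.5, 0.5), 1, 2))
  expect_warning(tm <- edgeT(c1, c2), "zero variance")
  expect_equal(tm@t[1, 1], 0)          # constant nonzero difference
  expect_equal(tm@t[1, 2], 0)          # exactly equal conditions
  # alternating differences: zero mean, honest t = 0
  c3 <- lapply(1:4, function(i) matrix(0.5 + c(1, -1, 1, -1)[i], 1, 1))
  c4 <- lapply(1:4, function(i) matrix(0.5, 1, 1))
  expect_equal(edgeT(c3, c4)@t[1, 1], 0)
  expect_error(edgeT(c1, c2[1:2]), "same dyads")
})

test_that("suprathreshold clustering separates signs and joins shared nodes", {
  t <- matrix(0, 3, 3)
  expect_length(suprathresholdClusters(t), 0)
  # edges (A1,B1) and (A1,B2) share node A1: one positive cluster
  t[1, 1] <- 2.5; t[1, 2] <- 3.0
  cl <- suprathresholdClusters(t)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$edges), 2)
  expect_equal(cl[[1]]$mass, 5.5)
  # opposite signs never merge even on a shared node
  t[1, 2] <- -3.0
  cl2 <- suprathresholdClusters(t)
  expect_length(cl2, 2)
  expect_setequal(vapply(cl2, `[[`, numeric(1), "sign"), c(1, -1))
  # disconnected same-sign edges form separate clusters
  t <- matrix(0, 3, 3); t[1, 1] <- 2.5; t[3, 3] <- 2.5
  expect_length(suprathresholdClusters(t), 2)
})

test_that("identical conditions give an all-zero null and no significance", {
  set.seed(2)
  mats <- nullMatrices(6, 4, 4)
  expect_warning(res <- nbsTest(mats, mats, nPerm = 200, seed = 1))
  expect_equal(max(nullDistribution(res)), 0)
  expect_length(significantClusters(res), 0)
})

test_that("small cohorts switch to exhaustive enumeration, seed-independent", {
  set.seed(3)
  c1 <- nullMatrices(4, 3, 3)
  c2 <- nullMatrices(4, 3, 3)
  n1 <- permutationNull(c1, c2, nPerm = 500, seed = 1)
  n2 <- permutationNull(c1, c2, nPerm = 500, seed = 99)
  expect_true(attr(n1, "exhaustive"))
  expect_equal(attr(n1, "nPerm"), 16L)
  expect_identical(as.numeric(n1), as.numeric(n2))
})

test_that("the planted block effect is detected at fixed seed", {
  set.seed(31)
  edges <- cbind(c(1, 1, 2, 2, 3, 3), c(1, 2, 2, 3, 3, 1))
  c1 <- plantEffect(nullMatrices(20, 8, 8), edges, delta = 0.3)
  c2 <- nullMatrices(20, 8, 8)
  res <- nbsTest(c1, c2, nPerm = 500, seed = 7)
  sig <- significantClusters(res)
  expect_gte(length(sig), 1)
  covered <- do.call(rbind, lapply(sig, `[[`, "edges"))
  planted <- paste(edges[, 1], edges[, 2])
  expect_gte(sum(planted %in% paste(covered[, 1], covered[, 2])), 4)
  # observed mass clears the null 95th percentile
  obs <- max(abs(vapply(nbsClusters(res), `[[`, numeric(1), "mass")))
  expect_gt(obs, quantile(nullDistribution(res), 0.95))
})

test_that("p-values are invariant to channel relabeling", {
  set.seed(8)
  edges <- cbind(c(1, 1), c(1, 2))
  c1 <- plantEffect(nullMatrices(12, 5, 5), edges, delta = 0.35)
  c2 <- nullMatrices(12, 5, 5)
  res <- nbsTest(c1, c2, nPerm = 300, seed = 5)
  permR <- sample(5); permC <- sample(5)
  c1p <- lapply(c1, function(m) m[permR, permC])
  c2p <- lapply(c2, function(m) m[permR, permC])
  resP <- nbsTest(c1p, c2p, nPerm = 300, seed = 5)
  p1 <- sort(vapply(nbsClusters(res), `[[`, numeric(1), "pFwer"))
  p2 <- sort(vapply(nbsClusters(resP), `[[`, numeric(1), "pFwer"))
  expect_equal(p1, p2)
})

test_that("alpha = 1 flags every cluster", {
  set.seed(9)
  c1 <- nullMatrices(8, 4, 4, lo = 0, hi = 1)
  c2 <- nullMatrices(8, 4, 4, lo = 0, hi = 1)
  res <- nbsTest(c1, c2, nPerm = 200, alpha = 1, seed = 2)
  expect_length(significantClusters(res), length(nbsClusters(res)))
})

test_that("missing edges are dropped before thresholding", {
  set.seed(10)
  c1 <- nullMatrices(6, 3, 3)
  c2 <- nullMatrices(6, 3, 3)
  c1 <- lapply(c1, function(m) { m[2, 2] <- NA; m })
  c2 <- lapply(c2, function(m) { m[2, 2] <- NA; m })
  res <- nbsTest(c1, c2, nPerm = 200, seed = 3)
  for (cl in nbsClusters(res))
    expect_false(any(cl$edges[, 1] == 2 & cl$edges[, 2] == 2))
})
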