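test_that("fitLinear reproduces exact and degenerate least-squares cases", {
  set.seed(2)
  X <- matrix(rnorm(150), 50, 3)
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta) + 4
  expect_lt(fitLinear(y, X)$rss, 1e-18)

  # response orthogonal to a zero-mean regressor: RSS = total SS about mean
  x1 <- rep(c(-1, 1), 25)
  y2 <- rnorm(50)
  y2 <- y2 - mean(y2)
  y2 <- y2 - x1 * sum(y2 * x1) / sum(x1^2)
  expect_equal(fitLinear(y2, cbind(x1))$rss, sum((y2 - mean(y2))^2))

  # normal-equations oracle on a random dense design
  y3 <- rnorm(50)
  Xi <- cbind(1, X)
  bHat <- solve(crossprod(Xi), crossprod(Xi, y3))
  rssOracle <- sum((y3 - Xi %*% bHat)^2)
  expect_equal(fitLinear(y3, X)$rss, rssOracle, tolerance = 1e-9)

  # rank-deficient design: warn, still return the (unique) minimal RSS
  Xd <- cbind(X, X[, 1])
  expect_warning(fd <- fitLinear(y3, Xd), "rank")
  expect_equal(fd$rss, rssOracle, tolerance = 1e-9)

  # all-constant response, no intercept: defined RSS, no crash
  expect_equal(fitLinear(rep(3, 50), cbind(x1), intercept = FALSE)$rss,
               sum((3 - x1 * sum(3 * x1) / sum(x1^2))^2))
})

test_that("fRatio, gcStrength and gcPValue follow their definitions", {
  expect_equal(fRatio(1, 1, 100, 10), 0)
  expect_equal(fRatio(2, 1, 102, 10), 8.2)
  expect_equal(fRatio(1.21, 1.0, 220, 10), 4.2)
  expect_warning(expect_equal(fRatio(1, 0, 100, 10), Inf), "Inf")
  expect_error(fRatio(1, 1, 20, 10), "nObs")

  expect_equal(gcStrength(1, 1), 0)
  expect_equal(gcStrength(exp(1) * 2, 2), 1)
  expect_equal(gcStrength(2, 1), log(2))
  expect_equal(gcStrength(1 - 1e-14, 1), 0)   # jitter clipped
  expect_error(gcStrength(0, 1), "positive")

  expect_equal(gcPValue(0, 100, 10), 1)
  expect_equal(gcPValue(qf(0.5, 10, 80), 100, 10), 0.5)
  expect_error(gcPValue(1, 20, 10), "nObs")

  # strength and F order pairs identically at fixed nObs, m
  set.seed(3)
  rssU <- 1
  rssR <- 1 + sort(runif(20))
  s <- log(rssR / rssU)
  f <- fRatio(rssR, rssU, 500, 5)
  expect_identical(order(s), order(f))
})

test_that("pairwiseConditionalGC detects constructed causality and nothing else", {
  detected <- logical(25)
  reverseQuiet <- logical(25)
  for (r in 1:25) {
    s <- causalToy(1500, seed = r)
    res <- pairwiseConditionalGC(s, p = 3, alpha = 0)
    S <- strengths(res)
    detected[r] <- pValues(res)[2, 1] < 0.01 && S[2, 1] > 10 * S[1, 2]
    reverseQuiet[r] <- pValues(res)[1, 2] > 0.01
  }
  expect_true(all(detected))
  expect_gte(mean(reverseQuiet), 0.9)
})

test_that("alpha=0 estimation equals the independent lag-matrix oracle", {
  set.seed(7)
  s4 <- matrix(rnorm(4 * 2000), 4)
  s4[2, -1] <- s4[2, -1] + 0.5 * s4[1, -2000]
  for (p in c(2, 5)) {
    pkg <- strengths(pairwiseConditionalGC(s4, p = p, alpha = 0))
    oracle <- lagMatrixOracleGC(s4, p)
    expect_equal(pkg, oracle, tolerance = 1e-8)
  }
  # mvarGC is definitionally the alpha = 0 configuration
  expect_equal(strengths(mvarGC(s4, 3)),
               strengths(pairwiseConditionalGC(s4, 3, alpha = 0)))
})

test_that("restricted RSS never falls below unrestricted RSS", {
  for (a in c(0, 0.4, 0.6)) {
    set.seed(11)
    s <- matrix(rnorm(5 * 1500), 5)
    s[3, -1] <- s[3, -1] + 0.4 * s[1, -1500]
    res <- pairwiseConditionalGC(s, p = 4, alpha = a)
    diffs <- sweep(res@rssRestricted, 1, res@rssUnrestricted, "-")
    expect_true(all(diffs >= -1e-7 * res@rssUnrestricted, na.rm = TRUE))
  }
})

test_that("degenerate and invalid inputs are handled explicitly", {
  set.seed(13)
  base <- matrix(rnorm(3 * 800), 3)
  dup <- rbind(base, base[1, ])     # duplicated channel
  res <- pairwiseConditionalGC(dup, p = 2, alpha = 0)
  expect_true(all(is.finite(strengths(res)[row(diag(4)) != col(diag(4))])))

  expect_error(pairwiseConditionalGC(base[, 1:20], p = 5, alpha = 0.5),
               "T >=")
  bad <- base
  bad[2, 5] <- NA
  expect_error(pairwiseConditionalGC(bad, p = 2, alpha = 0), "finite")
  expect_error(pairwiseConditionalGC(base[1, , drop = FALSE], p = 2,
                                     alpha = 0), "channels")
})

test_that("null p-values are calibrated at the nominal level", {
  # 8 independent 17-channel white-noise systems, 272 ordered pairs each
  pv <- c()
  for (r in 1:8) {
    set.seed(100 + r)
    s <- matrix(rnorm(17 * 5000), 17)
    res <- pairwiseConditionalGC(s, p = 3, alpha = 0.5)
    pv <- c(pv, pValues(res)[row(diag(17)) != col(diag(17))])
  }
  n <- length(pv)
  expect_gte(n, 2000)
  hits <- sum(pv < 0.05)
  band <- qbinom(c(0.025, 0.975), n, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
  # and approximately uniform overall
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("time-shuffling the source destroys detected strength", {
  s <- causalToy(2000, seed = 21)
  res <- pairwiseConditionalGC(s, p = 3, alpha = 0)
  sOrig <- strengths(res)[2, 1]
  shuffled <- numeric(10)
  for (r in 1:10) {
    set.seed(300 + r)
    sp <- s
    sp[1, ] <- sp[1, sample(ncol(sp))]
    shuffled[r] <- strengths(pairwiseConditionalGC(sp, p = 3,
                                                   alpha = 0))[2, 1]
  }
  expect_gt(sOrig, 10 * median(shuffled))
})

test_that("AIC recovers the order of an exact vector autoregression", {
  recovered <- integer(20)
  for (r in 1:20) {
    set.seed(400 + r)
    L <- 3; Tn <- 5000
    A1 <- diag(0.4, L); A2 <- matrix(0, L, L); A3 <- matrix(0, L, L)
    A2[1, 2] <- 0.3; A3[2, 3] <- -0.35; A3[3, 3] <- 0.3
    x <- matrix(0, L, Tn)
    for (t in 4:Tn)
      x[, t] <- A1 %*% x[, t - 1] + A2 %*% x[, t - 2] +
        A3 %*% x[, t - 3] + rnorm(L)
    recovered[r] <- aicOrderSelection(x, 1:6)$order
  }
  expect_gte(mean(recovered == 3), 0.9)

  # white noise prefers the smallest order offered
  picks <- integer(10)
  for (r in 1:10) {
    set.seed(500 + r)
    picks[r] <- aicOrderSelection(matrix(rnorm(3 * 2000), 3), 1:4)$order
  }
  expect_gt(mean(picks == 1), 0.5)

  expect_identical(aicOrderSelection(causalToy(500), 3)$order, 3L)
  expect_error(aicOrderSelection(causalToy(500), integer(0)), "non-empty")
})
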