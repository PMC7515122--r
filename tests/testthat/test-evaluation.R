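test_that("rocAuc matches hand-countable cases and the pairwise oracle", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(c(1, 2, 3, 10), c(1, 1, 0, 0)), 0)
  expect_equal(rocAuc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)  # ties half

  for (r in 1:25) {
    set.seed(600 + r)
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), 1)            # force some ties
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    expect_equal(rocAuc(scores, truth), bruteForceAuc(scores, truth))
  }
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rocAuc is invariant to strictly monotone score transforms", {
  set.seed(33)
  scores <- rnorm(100)
  truth <- rbinom(100, 1, 0.3)
  a <- rocAuc(scores, truth)
  expect_equal(rocAuc(exp(scores), truth), a)
  expect_equal(rocAuc(5 * scores - 2, truth), a)
  expect_equal(rocAuc(rank(scores), truth), a)
})

test_that("rocAuc agrees with an established ROC implementation", {
  set.seed(34)
  scores <- rnorm(200)
  truth <- rbinom(200, 1, 0.35)
  expect_equal(rocAuc(scores, truth),
               as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("benchmarkDensity pools links and is seed-deterministic", {
  cfg <- tinySimConfig()
  bm <- benchmarkDensity(0.2, nNetworks = 2, L = 3, p = 2,
                         alphas = 0.5, config = cfg, masterSeed = 5)
  expect_identical(bm$nLinks, 12L)          # (9 - 3) * 2
  expect_named(bm$pooledAuc, c("0", "0.5"))
  expect_true(all(bm$pooledAuc >= 0 & bm$pooledAuc <= 1))
  bm2 <- benchmarkDensity(0.2, nNetworks = 2, L = 3, p = 2,
                          alphas = 0.5, config = cfg, masterSeed = 5)
  expect_identical(bm, bm2)

  # single-network pooled AUC equals the per-network AUC
  bm1 <- benchmarkDensity(0.2, nNetworks = 1, L = 4, p = 2,
                          alphas = 0.5, config = cfg, masterSeed = 6)
  expect_equal(unname(bm1$pooledAuc["0.5"]),
               unname(bm1$perNetworkAuc["0.5", 1]))
})

test_that("alphaDensitySweep produces consistent grids with zero alpha baseline", {
  sw <- alphaDensitySweep(c(0.15, 0.3), alphas = c(0, 0.3, 0.6),
                          nNetworks = 2, L = 4, p = 2,
                          config = tinySimConfig(), masterSeed = 9)
  expect_s4_class(sw, "SweepResult")
  expect_identical(dim(deltaAuc(sw)), c(2L, 3L))
  # the alpha = 0 column of deltaAUC is identically zero by definition
  expect_lt(max(abs(deltaAuc(sw)[, "0"])), 1e-8)
  expect_lt(max(abs(deltaAuc(sw, "median")[, "0"])), 1e-8)
  sw2 <- alphaDensitySweep(c(0.15, 0.3), alphas = c(0, 0.3, 0.6),
                           nNetworks = 2, L = 4, p = 2,
                           config = tinySimConfig(), masterSeed = 9)
  expect_equal(deltaAuc(sw2), deltaAuc(sw))

  tab <- sweepTable(sw)
  expect_setequal(names(tab),
                  c("density", "alpha", "network", "method", "auc"))
  expect_identical(nrow(tab), 2L * 3L * 2L + 2L * 2L)
})

test_that("logTransform is elementwise log with located errors", {
  expect_equal(logTransform(matrix(1, 3, 3)), matrix(0, 3, 3))
  expect_equal(logTransform(matrix(c(exp(1), exp(2)), 1)),
               matrix(c(1, 2), 1))
  bad <- matrix(1, 2, 4)
  bad[2, 3] <- -1
  expect_error(logTransform(bad), "channel 2, time 3")

  set.seed(41)
  env <- matrix(rlnorm(2000, sdlog = 1.2), 4)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skew(as.vector(logTransform(env)))),
            abs(skew(as.vector(env))))
})

test_that("topPercentileEdges keeps the ceiling of the top fraction", {
  set.seed(42)
  stack <- replicate(5, {
    m <- matrix(runif(17 * 17), 17)
    diag(m) <- NA
    m
  }, simplify = FALSE)
  top <- topPercentileEdges(stack, 0.03)
  expect_identical(nrow(top), 9L)            # ceiling(0.03 * 272)
  expect_true(all(top$source != top$target))
  expect_true(all(diff(top$medianStrength) <= 0))

  # median across subjects is what gets ranked
  med <- apply(simplify2array(stack), c(1, 2), median)
  expect_equal(top$medianStrength[1],
               max(med[row(med) != col(med)]))

  allEdges <- topPercentileEdges(stack, 0.999)
  expect_identical(nrow(allEdges), 272L)

  single <- matrix(1:16, 4)
  one <- topPercentileEdges(single, 0.1)
  expect_equal(one$medianStrength,
               sort(single[row(single) != col(single)],
                    decreasing = TRUE)[seq_len(nrow(one))])
  expect_error(topPercentileEdges(list(), 0.03), "empty")
  expect_error(topPercentileEdges(single, 1.2), "topFraction")
})
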