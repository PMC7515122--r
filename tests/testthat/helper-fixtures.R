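# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

# x drives y with a one-sample lag; z is an independent bystander.
causalToy <- function(Tn = 2000, seed = 1, gain = 1, noise = 0.3) {
  set.seed(seed)
  x <- rnorm(Tn)
  y <- c(0, gain * x[-Tn]) + noise * rnorm(Tn)
  z <- rnorm(Tn)
  rbind(x = x, y = y, z = z)
}

# brute-force conditional MVAR-GC with explicit lag-matrix regressors;
# written independently of the package's Gram/Laguerre path
lagMatrixOracleGC <- function(series, p) {
  L <- nrow(series)
  Tn <- ncol(series)
  cs <- series - rowMeans(series)
  rows <- p:(Tn - 1)
  X <- do.call(cbind, lapply(1:p, function(l) t(cs[, rows - l + 1,
                                                  drop = FALSE])))
  S <- matrix(NA_real_, L, L)
  for (i in 1:L) {
    y <- cs[i, rows + 1]
    rssu <- sum(lm.fit(cbind(1, X), y)$residuals^2)
    for (j in (1:L)[-i]) {
      dropCols <- (0:(p - 1)) * L + j
      rssr <- sum(lm.fit(cbind(1, X[, -dropCols, drop = FALSE]),
                         y)$residuals^2)
      S[i, j] <- log(rssr / rssu)
    }
  }
  S
}

# all-pairs comparison count, the textbook AUC definition
bruteForceAuc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

tinySimConfig <- function(seed = 1L, nPoints = 800L) {
  simConfig(nPoints = as.integer(nPoints), burnIn = 200L,
            seed = as.integer(seed))
}
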