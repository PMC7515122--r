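#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, computed as the normalised
#' Mann-Whitney rank statistic with ties counted half. Equivalent to
#' sweeping a decision threshold over the scores and integrating the ROC
#' curve.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param truth binary labels (0/1 or logical), same length.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))   # 0.75
#' @export
rocAuc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' lengths differ")
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  nPos <- sum(truth == 1L)
  nNeg <- sum(truth == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[truth == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.offDiagonal <- function(M) M[row(M) != col(M)]

#' Benchmark both estimators at one network density
#'
#' Simulates \code{nNetworks} independent random networks at the given
#' density, runs the Laguerre estimator at each requested alpha and the
#' classical MVAR baseline (alpha = 0) on the identical series, and scores
#' the off-diagonal strengths against the ground-truth adjacency. Both the
#' pooled-links AUC (all candidate links of all networks pooled before the
#' ROC) and per-network AUCs (for median/IQR summaries) are returned.
#'
#' @param density network density.
#' @param nNetworks networks to simulate (benchmark default 32).
#' @param L nodes per network (benchmark default 17).
#' @param p model order for both estimators.
#' @param alphas Laguerre decay values to evaluate (alpha = 0 is always
#'   added as the MVAR baseline).
#' @param config a \code{\linkS4class{SimConfig}} template; its seed is
#'   overridden per network from \code{masterSeed}.
#' @param masterSeed integer master seed.
#' @return list with \code{pooledAuc} (named by alpha), \code{perNetworkAuc}
#'   (matrix alpha x network), \code{strengths} (list per alpha of pooled
#'   score vectors), \code{truth} (pooled 0/1 labels), and \code{nLinks}.
#' @export
benchmarkDensity <- function(density, nNetworks = 32L, L = 17L, p = 10L,
                             alphas = 0.595, config = simConfig(),
                             masterSeed = 1L) {
  alphas <- sort(unique(c(0, alphas)))
  nets <- networkFamily(L, density, nNetworks, masterSeed)
  simSeeds <- .deriveSeeds(masterSeed, nNetworks, "generic")
  scoreList <- lapply(alphas, function(a) c())
  names(scoreList) <- as.character(alphas)
  truth <- c()
  perNet <- matrix(NA_real_, length(alphas), nNetworks,
                   dimnames = list(as.character(alphas), NULL))
  for (k in seq_len(nNetworks)) {
    cfg <- config
    cfg@seed <- simSeeds[k]
    sim <- tryCatch(simulateNetwork(nets[[k]], cfg),
                    error = function(e)
                      stop("network ", k, ": ", conditionMessage(e)))
    labs <- .offDiagonal(adjacency(nets[[k]]))
    truth <- c(truth, labs)
    for (ai in seq_along(alphas)) {
      res <- tryCatch(
        pairwiseConditionalGC(seriesMatrix(sim), p = p,
                              alpha = alphas[ai]),
        error = function(e)
          stop("network ", k, ", alpha ", alphas[ai], ": ",
               conditionMessage(e)))
      sc <- .offDiagonal(strengths(res))
      scoreList[[ai]] <- c(scoreList[[ai]], sc)
      perNet[ai, k] <- rocAuc(sc, labs)
    }
  }
  pooled <- vapply(scoreList, rocAuc, numeric(1), truth = truth)
  list(pooledAuc = pooled, perNetworkAuc = perNet,
       strengths = scoreList, truth = truth, nLinks = length(truth))
}

#' Sweep estimator performance over densities and alphas
#'
#' For each density, simulates a family of networks once, computes the
#' MVAR baseline (alpha = 0) once per network, then evaluates the Laguerre
#' estimator at every alpha on the same series. Returns AUC grids and the
#' performance gain deltaAUC = AUC(LGC) - AUC(MVAR-GC) under both the
#' pooled-links and per-network-median aggregations.
#'
#' @param densities numeric vector of densities.
#' @param alphas numeric vector of alphas (0 is added if absent).
#' @param nNetworks networks per density.
#' @param L nodes per network.
#' @param p model order.
#' @param config \code{\linkS4class{SimConfig}} template.
#' @param masterSeed integer master seed.
#' @return a \code{\linkS4class{SweepResult}}.
#' @export
alphaDensitySweep <- function(densities, alphas = defaultAlphaGrid(),
                              nNetworks = 32L, L = 17L, p = 10L,
                              config = simConfig(), masterSeed = 1L) {
  alphas <- sort(unique(c(0, alphas)))
  nd <- length(densities); na <- length(alphas)
  aucLGC <- array(NA_real_, c(nd, na, nNetworks),
                  dimnames = list(signif(densities, 4),
                                  as.character(alphas), NULL))
  aucMVAR <- matrix(NA_real_, nd, nNetworks,
                    dimnames = list(signif(densities, 4), NULL))
  pooledL <- matrix(NA_real_, nd, na,
                    dimnames = list(signif(densities, 4),
                                    as.character(alphas)))
  pooledM <- setNames(numeric(nd), signif(densities, 4))
  for (di in seq_along(densities)) {
    bm <- benchmarkDensity(densities[di], nNetworks = nNetworks, L = L,
                           p = p, alphas = alphas, config = config,
                           masterSeed = masterSeed + di - 1L)
    aucMVAR[di, ] <- bm$perNetworkAuc["0", ]
    pooledM[di] <- bm$pooledAuc["0"]
    for (ai in seq_along(alphas)) {
      aucLGC[di, ai, ] <- bm$perNetworkAuc[as.character(alphas[ai]), ]
      pooledL[di, ai] <- bm$pooledAuc[as.character(alphas[ai])]
    }
  }
  medL <- apply(aucLGC, c(1, 2), stats::median)
  dPooled <- sweep(pooledL, 1, pooledM, "-")
  dMedian <- sweep(medL, 1, apply(aucMVAR, 1, stats::median), "-")
  new("SweepResult", densities = densities, alphas = alphas,
      aucLGC = aucLGC, aucMVAR = aucMVAR, pooledAucLGC = pooledL,
      pooledAucMVAR = pooledM, deltaAucPooled = dPooled,
      deltaAucMedian = dMedian, order = as.integer(p),
      seed = as.integer(masterSeed))
}

#' Default alpha grid for benchmarking sweeps
#'
#' 0 to 0.7 in steps of 0.05, plus 0.595 (the value highlighted in the
#' low-density ROC comparison).
#'
#' @return increasing numeric vector.
#' @export
defaultAlphaGrid <- function() {
  sort(unique(c(seq(0, 0.7, by = 0.05), 0.595)))
}

#' Elementwise natural-log transform of power envelopes
#'
#' Band-limited power envelopes are strongly right-skewed; taking the
#' natural log before estimation brings them closer to symmetry.
#'
#' @param envelopes numeric matrix with strictly positive entries.
#' @return matrix of the same shape.
#' @export
logTransform <- function(envelopes) {
  envelopes <- as.matrix(envelopes)
  bad <- which(envelopes <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("nonpositive entry at channel ", bad[1, 1], ", time ",
         bad[1, 2], "; log transform requires positive envelopes")
  log(envelopes)
}

#' Extract the strongest edges across a stack of subjects
#'
#' Takes the elementwise median of per-subject L x L strength matrices,
#' then keeps the \code{ceiling(topFraction * L * (L - 1))} off-diagonal
#' edges with the highest median strength. Ties are broken by (source,
#' target) index order.
#'
#' @param strengthStack list of L x L matrices (one per subject), or a
#'   single matrix.
#' @param topFraction fraction of ordered off-diagonal pairs to keep,
#'   in (0, 1); 0.03 keeps the top 3 percent.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{medianStrength}, ordered by decreasing strength.
#' @export
topPercentileEdges <- function(strengthStack, topFraction = 0.03) {
  if (is.matrix(strengthStack)) strengthStack <- list(strengthStack)
  if (length(strengthStack) == 0L) stop("empty strength stack")
  if (topFraction <= 0 || topFraction >= 1)
    stop("'topFraction' must be in (0, 1)")
  L <- nrow(strengthStack[[1]])
  med <- apply(simplify2array(strengthStack), c(1, 2), stats::median)
  ij <- which(row(med) != col(med), arr.ind = TRUE)
  df <- data.frame(source = ij[, 2], target = ij[, 1],
                   medianStrength = med[ij])
  nKeep <- ceiling(topFraction * L * (L - 1))
  ord <- order(-df$medianStrength, df$source, df$target)
  out <- df[ord[seq_len(nKeep)], ]
  rownames(out) <- NULL
  out
}
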