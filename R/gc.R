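#' Least-squares fit returning residual sum of squares
#'
#' QR-based least squares of \code{target} on \code{regressors}. Rank
#' deficiency is handled by a minimum-norm solution through the
#' pseudoinverse (with a warning); the fitted values, and hence the RSS,
#' are unaffected by which solution in the optimal set is returned.
#'
#' @param target numeric response vector.
#' @param regressors numeric design matrix, one row per observation.
#' @param intercept add an intercept column (default \code{TRUE}).
#' @return list with \code{rss}, \code{coefficients}, and \code{rank}.
#' @export
fitLinear <- function(target, regressors, intercept = TRUE) {
  X <- as.matrix(regressors)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least ncol + 1 rows (", ncol(X) + 1L,
         "), got ", nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient design (rank ", qrX$rank, " < ", ncol(X),
            "); returning minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], target)) / sv$d[pos])
    fitted <- X %*% coef
  } else {
    coef <- qr.coef(qrX, target)
    fitted <- X %*% coef
  }
  res <- target - fitted
  list(rss = sum(res^2), coefficients = drop(coef), rank = qrX$rank)
}

#' Granger F ratio from nested residual sums of squares
#'
#' \eqn{f = \frac{RSS_r - RSS_{ur}}{RSS_{ur}} \cdot \frac{N_{obs} - 2m}{m}},
#' the statistic comparing a restricted model against the unrestricted
#' model it is nested in, where m coefficients were removed.
#'
#' @param rssR restricted-model RSS.
#' @param rssUR unrestricted-model RSS.
#' @param nObs number of regression rows.
#' @param m number of coefficients removed.
#' @return the F statistic (\code{Inf} with a warning when rssUR is 0).
#' @export
fRatio <- function(rssR, rssUR, nObs, m) {
  if (nObs <= 2 * m) stop("'nObs' must exceed 2 * m")
  if (any(rssUR == 0)) {
    warning("unrestricted RSS is zero; returning +Inf")
    return(ifelse(rssUR == 0, Inf,
                  (rssR - rssUR) / rssUR * (nObs - 2 * m) / m))
  }
  (rssR - rssUR) / rssUR * (nObs - 2 * m) / m
}

#' Granger-causality strength
#'
#' Natural log of the restricted-to-unrestricted RSS ratio,
#' \eqn{s = \ln(RSS_r / RSS_{ur})}. Nested least squares on identical rows
#' guarantees the ratio is >= 1; values negative by floating-point jitter
#' are clipped to 0 with a warning.
#'
#' @param rssR restricted-model RSS, positive.
#' @param rssUR unrestricted-model RSS, positive.
#' @return nonnegative strength in natural-log units.
#' @export
gcStrength <- function(rssR, rssUR) {
  if (any(rssR <= 0) || any(rssUR <= 0))
    stop("residual sums of squares must be positive")
  s <- log(rssR / rssUR)
  if (any(s < 0)) {
    if (any(s < -1e-8))
      warning("restricted RSS below unrestricted beyond jitter; clipping")
    s <- pmax(s, 0)
  }
  s
}

#' P-value of the Granger F test
#'
#' Upper-tail probability of the F statistic under the null of no
#' improvement, using the Fisher-Snedecor distribution with numerator
#' df = m (coefficients removed) and denominator df = nObs - 2m. (The
#' denominator-first ordering "Nobs - 2m and m" seen in some write-ups
#' refers to the same test; the ordering used here is the one under which
#' null p-values are uniform.)
#'
#' @param f F statistic, >= 0.
#' @param nObs number of regression rows.
#' @param m coefficients removed per test.
#' @return p-value in (0, 1].
#' @export
gcPValue <- function(f, nObs, m) {
  if (nObs <= 2 * m) stop("'nObs' must exceed 2 * m")
  if (any(f < 0, na.rm = TRUE)) stop("'f' must be >= 0")
  stats::pf(f, df1 = m, df2 = nObs - 2 * m, lower.tail = FALSE)
}

## Gram-matrix machinery: with tens of thousands of rows shared by every
## nested fit, RSS for any column subset S follows from
## RSS = y'y - (X_S'y)' G_SS^{-1} (X_S'y) with G = X'X computed once.
.rssFromGram <- function(G, Xty, yty, cols) {
  Gs <- G[cols, cols, drop = FALSE]
  bs <- Xty[cols, , drop = FALSE]
  sol <- tryCatch(chol2inv(chol(Gs)) %*% bs, error = function(e) NULL)
  if (is.null(sol)) {
    # rank-deficient subset: minimum-norm via eigen pseudoinverse
    eg <- eigen(Gs, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * length(cols) * .Machine$double.eps
    sol <- eg$vectors[, pos, drop = FALSE] %*%
      (crossprod(eg$vectors[, pos, drop = FALSE], bs) / eg$values[pos])
  }
  pmax(yty - colSums(bs * sol), 0)
}

#' Pairwise fully conditioned Granger causality in the Laguerre basis
#'
#' For every ordered channel pair (source j, target i) of an L x T series,
#' fits the unrestricted model predicting \eqn{x_i(t+1)} from the p
#' Laguerre regressors of every channel (all other channels condition the
#' test), and the restricted model with source j's p regressors removed,
#' on the identical row window \eqn{t \in [N, T-2]} (0-based). Strength,
#' F ratio and p-value per pair follow from the two residual sums of
#' squares. With \code{alpha = 0} the regressors are (signed) plain lags
#' and the procedure is exactly classical conditional MVAR-GC.
#'
#' Channels are mean-centered before filtering and an intercept is kept in
#' the design; regressor columns are rescaled to unit standard deviation
#' for conditioning (RSS is invariant to column scaling).
#'
#' @param series numeric L x T matrix, channels in rows.
#' @param p model order (Laguerre orders 0..p-1 per channel).
#' @param alpha Laguerre decay in [0, 1); 0 gives classical MVAR-GC.
#' @param maxMemory cap on basis memory (default 2000).
#' @param intercept keep an intercept column (default \code{TRUE}).
#' @return a \code{\linkS4class{GCResult}}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(3 * 500), 3)
#' x[2, -1] <- x[2, -1] + 0.8 * x[1, -500]   # 1 -> 2
#' res <- pairwiseConditionalGC(x, p = 2, alpha = 0)
#' strengths(res)
#' @export
pairwiseConditionalGC <- function(series, p, alpha, maxMemory = 2000L,
                                  intercept = TRUE) {
  series <- as.matrix(series)
  if (!all(is.finite(series))) stop("'series' must be finite")
  L <- nrow(series)
  Tn <- ncol(series)
  if (L < 2L) stop("need at least 2 channels")
  basis <- buildBasis(p, alpha, maxMemory = maxMemory)
  N <- basis@memory
  nPar <- L * p + as.integer(intercept)
  minT <- N + nPar + 2L
  if (Tn - N - 1L <= nPar)
    stop("series too short: T = ", Tn, " but T >= ", minT,
         " required for L = ", L, ", p = ", p, ", alpha = ", alpha,
         " (basis memory N = ", N, ")")

  centered <- series - rowMeans(series)
  rows <- (N + 1L):(Tn - 1L)          # 1-based t; predict t + 1
  nObs <- length(rows)
  # regressor block for channel ch occupies columns (ch-1)*p + 1 .. ch*p
  X <- matrix(0, nObs, L * p)
  for (ch in seq_len(L)) {
    feats <- laguerreFilter(centered[ch, ], basis)
    X[, (ch - 1L) * p + seq_len(p)] <- t(feats[, rows, drop = FALSE])
  }
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  X <- sweep(X, 2, sds, "/")
  if (intercept) X <- cbind(1, X)
  off <- as.integer(intercept)
  Y <- t(centered[, rows + 1L, drop = FALSE])

  G <- crossprod(X)
  Xty <- crossprod(X, Y)
  yty <- colSums(Y^2)

  allCols <- seq_len(ncol(X))
  rssUR <- .rssFromGram(G, Xty, yty, allCols)
  rssR <- matrix(NA_real_, L, L)
  for (j in seq_len(L)) {
    cols <- allCols[-(off + (j - 1L) * p + seq_len(p))]
    rssR[, j] <- .rssFromGram(G, Xty, yty, cols)
  }
  # guard against exactly-zero RSS (deterministic response)
  tiny <- .Machine$double.xmin
  rssURc <- pmax(rssUR, tiny)
  s <- log(pmax(rssR, tiny) / rep(rssURc, L))
  dim(s) <- c(L, L)
  s <- pmax(s, 0)
  f <- sweep(sweep(rssR, 1, rssUR, "-"), 1, rssURc, "/") *
    (nObs - 2 * p) / p
  f <- pmax(f, 0)
  pv <- matrix(gcPValue(as.vector(f), nObs, p), L, L)
  diag(s) <- NA_real_
  diag(f) <- NA_real_
  diag(pv) <- NA_real_
  diag(rssR) <- NA_real_

  new("GCResult", strengths = s, fRatios = f, pValues = pv,
      rssUnrestricted = as.numeric(rssUR), rssRestricted = rssR,
      nObs = as.integer(nObs), m = as.integer(p), order = as.integer(p),
      alpha = alpha, memory = N)
}

#' Classical conditional MVAR Granger causality
#'
#' The classical lagged multivariate autoregressive Granger causality,
#' i.e. \code{\link{pairwiseConditionalGC}} at \code{alpha = 0}, where the
#' Laguerre regressors reduce to signed copies of lags 1..p.
#'
#' @inheritParams pairwiseConditionalGC
#' @return a \code{\linkS4class{GCResult}}.
#' @export
mvarGC <- function(series, p, intercept = TRUE) {
  pairwiseConditionalGC(series, p = p, alpha = 0, intercept = intercept)
}

#' AIC order selection for the full multivariate lagged model
#'
#' Fits the full multivariate autoregression (all channels jointly,
#' explicit lags, i.e. the \code{alpha = 0} configuration) for each
#' candidate order on a common row window determined by the largest
#' order, and returns the order minimising
#' \eqn{AIC(q) = N_{obs} \log\det\hat\Sigma_q + 2 k_q} where
#' \eqn{\hat\Sigma_q} is the residual covariance and
#' \eqn{k_q = L^2 q + L} the parameter count.
#'
#' @param series numeric L x T matrix.
#' @param orders integer vector of candidate orders (e.g. \code{1:20}).
#' @return list with \code{order} (the AIC minimiser), \code{aic}
#'   (named vector of AIC values), and \code{nObs}.
#' @export
aicOrderSelection <- function(series, orders) {
  if (length(orders) == 0L) stop("'orders' must be non-empty")
  orders <- sort(unique(as.integer(orders)))
  series <- as.matrix(series)
  L <- nrow(series)
  Tn <- ncol(series)
  pmax <- max(orders)
  if (Tn - pmax - 1L <= L * pmax + 1L)
    stop("series too short for maximum order ", pmax)
  centered <- series - rowMeans(series)
  rows <- pmax:(Tn - 1L)
  nObs <- length(rows)
  # lag blocks ordered by lag so order-q models are leading-column subsets
  X <- matrix(0, nObs, L * pmax)
  for (lag in seq_len(pmax))
    X[, (lag - 1L) * L + seq_len(L)] <- t(centered[, rows - lag + 1L,
                                                   drop = FALSE])
  X <- cbind(1, X)
  Y <- t(centered[, rows + 1L, drop = FALSE])
  G <- crossprod(X)
  Xty <- crossprod(X, Y)
  Yty <- crossprod(Y)
  aic <- vapply(orders, function(q) {
    cols <- 1:(1L + L * q)
    B <- tryCatch(chol2inv(chol(G[cols, cols])) %*% Xty[cols, ],
                  error = function(e) qr.solve(G[cols, cols], Xty[cols, ]))
    Ecov <- (Yty - crossprod(Xty[cols, ], B)) / nObs
    ld <- determinant(Ecov, logarithm = TRUE)
    nObs * as.numeric(ld$modulus) + 2 * (L^2 * q + L)
  }, numeric(1))
  names(aic) <- orders
  list(order = orders[which.min(aic)], aic = aic, nObs = nObs)
}
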