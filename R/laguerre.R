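#' Evaluate a discrete-time Laguerre function
#'
#' Computes \eqn{\phi_m(n) = \alpha^{(n-m)/2} (1-\alpha)^{1/2}
#' \sum_{j=0}^{m} (-1)^j \binom{n}{j} \binom{m}{j} \alpha^{m-j}
#' (1-\alpha)^j}, the m-th order discrete-time orthonormal Laguerre
#' function at lag n. The family is orthonormal over \eqn{n = 0, 1, \dots}
#' and decays like \eqn{\alpha^{n/2}}, so a single convolution per order
#' summarises arbitrarily long signal history.
#'
#' At \eqn{\alpha = 0} the convention \eqn{0^0 = 1} is used, under which the
#' family collapses to signed delayed deltas,
#' \eqn{\phi_m(n) = (-1)^m \delta_{nm}}: filtering with order p then spans
#' exactly the classical lag-1..p regressor space.
#'
#' Binomial coefficients are evaluated on the log scale, so large (m, n)
#' do not overflow.
#'
#' @param m order index, integer >= 0 (scalar).
#' @param n lag index, integer >= 0 (vectorised).
#' @param alpha decay parameter in [0, 1).
#' @return numeric vector of \eqn{\phi_m(n)}, same length as \code{n}.
#' @examples
#' laguerrePhi(0, 0, 0.595)   # sqrt(1 - 0.595)
#' laguerrePhi(1, 1, 0)       # -1 (delta collapse)
#' @export
laguerrePhi <- function(m, n, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("'alpha' must be a single value in [0, 1)")
  if (length(m) != 1L || m < 0 || m != round(m))
    stop("'m' must be a single nonnegative integer")
  if (any(n < 0) || any(n != round(n)))
    stop("'n' must be nonnegative integers")
  if (alpha == 0) {
    # 0^0 = 1 convention: only the j = m term survives, and alpha^{(n-m)/2}
    # is 1 at n = m and 0 at n > m; n < m is taken as 0 by the same limit.
    return(ifelse(n == m, (-1)^m, 0))
  }
  la <- log(alpha)
  l1a <- log1p(-alpha)
  vapply(n, function(ni) {
    j <- 0:min(m, ni)
    terms <- (-1)^j * exp(lchoose(ni, j) + lchoose(m, j) +
                          (m - j) * la + j * l1a)
    alpha^((ni - m) / 2) * sqrt(1 - alpha) * sum(terms)
  }, numeric(1))
}

#' Construct a Laguerre basis with automatic memory selection
#'
#' Tabulates \eqn{\phi_m(n)} for orders \eqn{m = 0, \dots, p - 1} and
#' chooses the truncation length N as the smallest lag beyond which every
#' order has decayed below \code{tol} in absolute value (capped at
#' \code{maxMemory}, with a warning if the cap binds before the decay
#' criterion is met). For \code{alpha = 0} this gives \code{N = p - 1}
#' exactly, the classical lag window.
#'
#' @param p number of basis functions (model order), integer >= 1.
#' @param alpha decay parameter in [0, 1).
#' @param maxMemory hard cap on N (default 2000 samples).
#' @param tol decay threshold defining N (default 1e-6).
#' @return a \code{\linkS4class{LaguerreBasis}}.
#' @examples
#' buildBasis(3, 0)       # N = 2, signed identity table
#' buildBasis(1, 0.5)     # N ~ 40
#' @export
buildBasis <- function(p, alpha, maxMemory = 2000L, tol = 1e-6) {
  if (p < 1) stop("'p' must be >= 1")
  p <- as.integer(p)
  maxMemory <- as.integer(maxMemory)
  if (alpha == 0) {
    N <- p - 1L
    phi <- matrix(0, p, N + 1L)
    phi[cbind(1:p, 1:p)] <- (-1)^(0:(p - 1L))
    return(new("LaguerreBasis", alpha = alpha, orderCount = p,
               memory = N, phi = phi))
  }
  nGrid <- 0:maxMemory
  phi <- t(vapply(0:(p - 1L), laguerrePhi, numeric(length(nGrid)),
                  n = nGrid, alpha = alpha))
  env <- apply(abs(phi), 2, max)
  # N = smallest n such that |phi_m(n')| < tol for every n' > n
  below <- rev(cumprod(rev(env < tol))) == 1
  if (!any(below[-1L])) {
    warning("memory cap ", maxMemory,
            " reached before basis decayed below ", tol)
    N <- maxMemory
  } else {
    N <- max(0L, min(which(below)) - 2L)  # last lag still retained
    N <- as.integer(N)
  }
  new("LaguerreBasis", alpha = alpha, orderCount = p, memory = N,
      phi = phi[, 1:(N + 1L), drop = FALSE])
}

#' Convolve a signal with a Laguerre basis
#'
#' Applies the first-order Volterra-Wiener expansion
#' \eqn{L_t^{(m)} = \sum_{n=0}^{N} \phi_m(n) x_{t-n}} to a 1-D signal,
#' producing one compact long-memory regressor row per order. Entries
#' with insufficient history (t < N in 0-based time) are \code{NA}, never
#' silently zero-padded.
#'
#' @param series numeric vector of length T > basis memory.
#' @param basis a \code{\linkS4class{LaguerreBasis}}.
#' @return a p x T numeric matrix; columns 1..N are \code{NA}.
#' @export
laguerreFilter <- function(series, basis) {
  stopifnot(is(basis, "LaguerreBasis"))
  Tn <- length(series)
  N <- basis@memory
  if (Tn < N + 2L)
    stop("series length ", Tn, " leaves no valid regression rows ",
         "(basis memory N = ", N, " requires length >= ", N + 2L, ")")
  out <- matrix(NA_real_, basis@orderCount, Tn)
  # embed() row t holds (x_t, x_{t-1}, ..., x_{t-N}); one BLAS product
  # evaluates the convolution for every order at every valid t
  E <- stats::embed(series, N + 1L)
  out[, (N + 1L):Tn] <- basis@phi %*% t(E)
  out
}
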