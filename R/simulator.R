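#' Create a simulator configuration
#'
#' Constructor for \code{\linkS4class{SimConfig}} with the benchmark
#' defaults: Euler step 0.25 s, noise gain 0.1, coupling strength 0.2
#' shared over a node's incoming edges, noise recursion order 3,
#' spectral exponent 1 (pure 1/f noise), integrator decay 8 and drive
#' 0.1, source delays uniform on 0-12 s, 10,000 retained points after a
#' 1000-sample burn-in.
#'
#' @param h integration step in seconds.
#' @param d noise gain.
#' @param wCoupling global coupling strength.
#' @param wNoise noise-model order.
#' @param beta spectral exponent of the 1/f^beta noise.
#' @param tau0 integrator time constant.
#' @param b integrator drive gain.
#' @param delayRange length-2 uniform delay range, seconds.
#' @param nPoints retained samples.
#' @param burnIn discarded initial samples.
#' @param seed integer seed for this realization.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(h = 0.25, d = 0.1, wCoupling = 0.2, wNoise = 3L,
                      beta = 1, tau0 = 8, b = 0.1,
                      delayRange = c(0, 12), nPoints = 10000L,
                      burnIn = 1000L, seed = 1L) {
  new("SimConfig", h = h, d = d, wCoupling = wCoupling,
      wNoise = as.integer(wNoise), beta = beta, tau0 = tau0, b = b,
      delayRange = delayRange, nPoints = as.integer(nPoints),
      burnIn = as.integer(burnIn), seed = as.integer(seed))
}

#' Fractional-difference noise coefficients
#'
#' The recursion \eqn{a_0 = 1}, \eqn{a_l = (l - 1 - \beta/2) a_{l-1} / l}
#' generates the coefficients of the truncated fractional-difference
#' filter whose output has a \eqn{1/f^\beta} power spectrum. \eqn{\beta = 0}
#' gives \eqn{a_l = 0} for l >= 1 (white noise).
#'
#' @param beta spectral exponent.
#' @param order truncation order (number of coefficients beyond a0).
#' @return numeric vector \code{c(a0, a1, ..., a_order)}.
#' @examples
#' noiseCoeffs(1, 3)   # 1, -0.5, -0.125, -0.0625
#' @export
noiseCoeffs <- function(beta, order) {
  if (order < 1) stop("'order' must be >= 1")
  a <- numeric(order + 1L)
  a[1] <- 1
  for (l in seq_len(order))
    a[l + 1L] <- (l - 1 - beta / 2) * a[l] / l
  a
}

#' Long-range-correlated noise series
#'
#' Generates \eqn{\xi(t) = \sum_{l=1}^{w} (-a_l) \xi(t - l) + d\,\epsilon(t)}
#' with \eqn{\epsilon \sim N(0, 1)} and zero initial history: an
#' autoregressive approximation to \eqn{1/f^\beta} noise. \eqn{\beta = 0}
#' reduces to i.i.d. normal noise scaled by d.
#'
#' @param n series length.
#' @param beta spectral exponent.
#' @param order noise-model order w.
#' @param d innovation gain.
#' @param seed integer seed.
#' @return numeric vector of length n.
#' @export
lrcNoise <- function(n, beta = 1, order = 3L, d = 0.1, seed = 1L) {
  if (n <= order) stop("'n' must exceed the noise order")
  a <- noiseCoeffs(beta, order)
  eps <- .withSeed(seed, stats::rnorm(n))
  as.numeric(stats::filter(d * eps, filter = -a[-1L],
                           method = "recursive"))
}

#' In-degree-normalised coupling matrix
#'
#' Converts a binary adjacency into coupling coefficients: node i with
#' k > 0 parents receives \code{wCoupling / k} from each, so every
#' non-isolated node's incoming coupling sums to \code{wCoupling}.
#'
#' @param network a \code{\linkS4class{DirectedNetwork}}.
#' @param wCoupling global coupling strength.
#' @return L x L numeric matrix with row sums in \{0, wCoupling\}.
#' @export
couplingMatrix <- function(network, wCoupling = 0.2) {
  A <- adjacency(network)
  indeg <- rowSums(A)
  C <- A * ifelse(indeg > 0, wCoupling / pmax(indeg, 1), 0)
  C
}

#' Simulate coupled long-memory node dynamics on a network
#'
#' Evolves, by explicit Euler steps of size h, one stochastic variable per
#' node driven by the increment of a long-range-correlated noise process,
#' damped by a cubic integral term, and coupled diffusively to leaky
#' integrators of its parent nodes with per-source delays:
#' \deqn{\eta_j \leftarrow \eta_j + h(-\eta_j/\tau_0 + b x_j)}
#' \deqn{x_i \leftarrow x_i + \xi_i(t) - \frac{h^2}{3} x_i^3 +
#'   h \sum_j c_{ij}\,(\eta_j(t - \tau_j) - x_i)}
#' The noise enters as the per-sample output of the fractional-difference
#' recursion (gain d applied once, inside the recursion); the cubic term
#' is the window integral \eqn{-h \int_{t-h}^{t} x^3/3\,ds} under a
#' left-rectangle rule; the coupling, a continuous-time force, is
#' multiplied by the step. Because x accumulates its noise, the cubic
#' term is what keeps trajectories symmetrically bounded around zero.
#' Source delays \eqn{\tau_j} are drawn once per realization, uniform
#' over the configured range, and rounded to whole samples. Noise,
#' delays and all other randomness derive deterministically from
#' \code{config@seed}.
#'
#' @param network a \code{\linkS4class{DirectedNetwork}}.
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return a \code{\linkS4class{SimOutput}} with \code{config@nPoints}
#'   retained columns (burn-in discarded).
#' @examples
#' net <- randomNetwork(5, 0.2, seed = 2)
#' out <- simulateNetwork(net, simConfig(nPoints = 500L, seed = 3L))
#' dim(seriesMatrix(out))
#' @export
simulateNetwork <- function(network, config) {
  stopifnot(is(network, "DirectedNetwork"), is(config, "SimConfig"))
  L <- nrow(adjacency(network))
  h <- config@h
  total <- config@burnIn + config@nPoints
  C <- couplingMatrix(network, config@wCoupling)
  rowC <- rowSums(C)

  noiseSeeds <- .deriveSeeds(config@seed, L, "noise")
  xi <- matrix(0, L, total)
  for (i in seq_len(L))
    xi[i, ] <- lrcNoise(total, beta = config@beta, order = config@wNoise,
                        d = config@d, seed = noiseSeeds[i])

  delaySec <- .withSeed(.deriveSeeds(config@seed, 1L, "delays"),
                        stats::runif(L, config@delayRange[1],
                                     config@delayRange[2]))
  lag <- as.integer(round(delaySec / h))

  x <- matrix(0, L, total)
  eta <- matrix(0, L, total)
  idx <- seq_len(L)
  h2over3 <- h^2 / 3
  for (t in seq_len(total - 1L)) {
    eta[, t + 1L] <- eta[, t] + h * (-eta[, t] / config@tau0 +
                                     config@b * x[, t])
    src <- t + 1L - lag
    etaDel <- ifelse(src >= 1L, eta[cbind(idx, pmax(src, 1L))], 0)
    xNew <- x[, t] + xi[, t + 1L] - h2over3 * x[, t]^3 +
      h * (as.numeric(C %*% etaDel) - rowC * x[, t])
    if (any(!is.finite(xNew)))
      stop("non-finite state at step ", t + 1L, ", node ",
           which(!is.finite(xNew))[1])
    x[, t + 1L] <- xNew
  }

  keep <- (config@burnIn + 1L):total
  new("SimOutput", x = x[, keep, drop = FALSE],
      eta = eta[, keep, drop = FALSE], delays = lag,
      coupling = C, config = config, network = network)
}
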