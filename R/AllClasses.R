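#' @import methods
NULL

#' Discrete-time Laguerre basis
#'
#' Holds the tabulated values of the discrete-time orthonormal Laguerre
#' functions \eqn{\phi_m(n)} for orders \eqn{m = 0, \dots, p-1} and lags
#' \eqn{n = 0, \dots, N}, together with the decay parameter \eqn{\alpha}
#' that controls their exponential memory. Convolving a signal with the
#' rows of \code{phi} compresses its entire recent history into \eqn{p}
#' regressors, one per order; \eqn{\alpha = 0} collapses the family to
#' (signed) delayed deltas, i.e. plain lagged copies of the signal.
#'
#' @slot alpha numeric decay parameter in \eqn{[0, 1)}.
#' @slot orderCount integer number of basis functions \eqn{p \ge 1}.
#' @slot memory integer truncation length \eqn{N} (lags \eqn{0..N}).
#' @slot phi numeric matrix, \code{orderCount} x \code{memory + 1}, with
#'   \code{phi[m + 1, n + 1]} = \eqn{\phi_m(n)}.
#'
#' @seealso \code{\link{buildBasis}}, \code{\link{laguerrePhi}},
#'   \code{\link{laguerreFilter}}
#' @export
setClass("LaguerreBasis",
  representation(
    alpha = "numeric",
    orderCount = "integer",
    memory = "integer",
    phi = "matrix"
  )
)

setValidity("LaguerreBasis", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must be a single value in [0, 1)")
  if (object@orderCount < 1L)
    msg <- c(msg, "'orderCount' must be >= 1")
  if (object@memory < 0L)
    msg <- c(msg, "'memory' must be >= 0")
  if (!identical(dim(object@phi),
                 c(as.integer(object@orderCount), object@memory + 1L)))
    msg <- c(msg, "'phi' must be orderCount x (memory + 1)")
  if (length(msg)) msg else TRUE
})

#' Conditional Granger-causality result
#'
#' Per-ordered-pair output of a fully conditioned Granger-causality scan
#' over an L-channel series: causal strengths
#' \eqn{s_{j \to i} = \ln(RSS_r / RSS_{ur})}, the corresponding F ratios and
#' upper-tail p-values, and the residual sums of squares of the restricted
#' and unrestricted models. Entry \code{[i, j]} always refers to the ordered
#' influence of source channel \eqn{j} on target channel \eqn{i}; diagonals
#' are \code{NA}.
#'
#' @slot strengths L x L numeric matrix of \eqn{s_{j \to i}} (natural-log
#'   units), diagonal \code{NA}.
#' @slot fRatios L x L numeric matrix of F statistics, diagonal \code{NA}.
#' @slot pValues L x L numeric matrix of upper-tail p-values, diagonal
#'   \code{NA}.
#' @slot rssUnrestricted length-L numeric, unrestricted-model RSS per target.
#' @slot rssRestricted L x L numeric matrix, \code{[i, j]} the restricted RSS
#'   when source j's regressors are removed from target i's model.
#' @slot nObs integer, number of valid regression rows.
#' @slot m integer, coefficients removed per test (the model order p).
#' @slot order integer model order p.
#' @slot alpha numeric Laguerre decay used (0 = classical lagged MVAR).
#' @slot memory integer basis memory N actually used.
#' @export
setClass("GCResult",
  representation(
    strengths = "matrix",
    fRatios = "matrix",
    pValues = "matrix",
    rssUnrestricted = "numeric",
    rssRestricted = "matrix",
    nObs = "integer",
    m = "integer",
    order = "integer",
    alpha = "numeric",
    memory = "integer"
  )
)

setValidity("GCResult", function(object) {
  L <- nrow(object@strengths)
  msg <- character()
  if (ncol(object@strengths) != L)
    msg <- c(msg, "'strengths' must be square")
  for (nm in c("fRatios", "pValues", "rssRestricted")) {
    if (!identical(dim(slot(object, nm)), c(L, L)))
      msg <- c(msg, sprintf("'%s' must match dim(strengths)", nm))
  }
  if (length(object@rssUnrestricted) != L)
    msg <- c(msg, "'rssUnrestricted' must have one entry per channel")
  off <- object@strengths[row(object@strengths) != col(object@strengths)]
  if (any(off < 0, na.rm = TRUE))
    msg <- c(msg, "off-diagonal strengths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Random directed ground-truth network
#'
#' Binary, zero-diagonal adjacency matrix \code{A} with \code{A[i, j] = 1}
#' when node j directly influences node i. Bidirectional pairs and cycles
#' are permitted. The number of edges equals
#' \code{round(density * L * (L - 1))} exactly.
#'
#' @slot adjacency L x L binary matrix (0/1, zero diagonal).
#' @slot nEdges integer edge count.
#' @slot density numeric requested edge density.
#' @slot seed integer seed the draw was made under.
#' @seealso \code{\link{randomNetwork}}, \code{\link{networkFamily}}
#' @export
setClass("DirectedNetwork",
  representation(
    adjacency = "matrix",
    nEdges = "integer",
    density = "numeric",
    seed = "integer"
  )
)

setValidity("DirectedNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  if (sum(A) != object@nEdges)
    msg <- c(msg, "nEdges must equal the number of ones in adjacency")
  if (length(msg)) msg else TRUE
})

#' Simulator configuration
#'
#' Parameters of the coupled stochastic node model: Euler step \code{h}
#' (seconds), noise gain \code{d}, global coupling strength \code{wCoupling}
#' (shared across incoming edges of a node, normalised by in-degree), noise
#' recursion order \code{wNoise}, spectral exponent \code{beta} of the
#' \eqn{1/f^\beta} noise, leaky-integrator decay \code{tau0} and drive gain
#' \code{b} of the coupling integral, the uniform source-delay range in
#' seconds, the number of retained points and the burn-in discarded before
#' retention.
#'
#' @slot h numeric integration step, seconds.
#' @slot d numeric noise gain.
#' @slot wCoupling numeric global coupling strength.
#' @slot wNoise integer noise-model order.
#' @slot beta numeric spectral exponent of the long-range-correlated noise.
#' @slot tau0 numeric integrator time constant.
#' @slot b numeric integrator drive gain.
#' @slot delayRange numeric length-2, uniform delay range in seconds.
#' @slot nPoints integer retained samples.
#' @slot burnIn integer discarded initial samples.
#' @slot seed integer master seed for this realization.
#' @seealso \code{\link{simConfig}}, \code{\link{simulateNetwork}}
#' @export
setClass("SimConfig",
  representation(
    h = "numeric",
    d = "numeric",
    wCoupling = "numeric",
    wNoise = "integer",
    beta = "numeric",
    tau0 = "numeric",
    b = "numeric",
    delayRange = "numeric",
    nPoints = "integer",
    burnIn = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@h <= 0) msg <- c(msg, "'h' must be > 0")
  if (length(object@delayRange) != 2L || any(object@delayRange < 0) ||
      diff(object@delayRange) < 0)
    msg <- c(msg, "'delayRange' must be nonnegative and ordered")
  if (object@nPoints <= 0L) msg <- c(msg, "'nPoints' must be > 0")
  if (object@burnIn < 0L) msg <- c(msg, "'burnIn' must be >= 0")
  if (object@wNoise < 1L) msg <- c(msg, "'wNoise' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulator output
#'
#' One realization of the coupled node model on a network: the retained
#' state series \code{x} (channels x time), the coupling integrator series
#' \code{eta}, the per-source delays realized for this draw (in samples),
#' and the in-degree-normalised coupling matrix.
#'
#' @slot x L x T numeric matrix of node states.
#' @slot eta L x T numeric matrix of integrator states.
#' @slot delays length-L integer, realized delay per source node, samples.
#' @slot coupling L x L numeric coupling matrix.
#' @slot config the \code{SimConfig} used.
#' @slot network the \code{DirectedNetwork} simulated on.
#' @export
setClass("SimOutput",
  representation(
    x = "matrix",
    eta = "matrix",
    delays = "integer",
    coupling = "matrix",
    config = "SimConfig",
    network = "DirectedNetwork"
  )
)

setValidity("SimOutput", function(object) {
  msg <- character()
  if (!all(is.finite(object@x))) msg <- c(msg, "'x' must be finite")
  if (!identical(dim(object@x), dim(object@eta)))
    msg <- c(msg, "'x' and 'eta' dims must agree")
  if (length(object@delays) != nrow(object@x))
    msg <- c(msg, "one delay per source node required")
  if (length(msg)) msg else TRUE
})

#' Density-by-alpha benchmarking sweep result
#'
#' AUC grids from a benchmarking sweep: per-(density, network) AUCs of the
#' Laguerre estimator for every alpha, the matching classical MVAR baseline
#' (computed once per network and reused across alpha), and the derived
#' delta-AUC = AUC(LGC) - AUC(MVAR-GC) under the two aggregations used for
#' reporting: pooled links across networks, and per-network median.
#'
#' @slot densities numeric vector of network densities swept.
#' @slot alphas numeric vector of Laguerre decay values swept.
#' @slot aucLGC 3-d array [density, alpha, network] of LGC AUCs.
#' @slot aucMVAR matrix [density, network] of MVAR-GC AUCs.
#' @slot pooledAucLGC matrix [density, alpha], pooled-links aggregation.
#' @slot pooledAucMVAR numeric per density, pooled-links aggregation.
#' @slot deltaAucPooled matrix [density, alpha].
#' @slot deltaAucMedian matrix [density, alpha], per-network-median
#'   aggregation.
#' @slot order integer model order shared by both estimators.
#' @slot seed integer master seed.
#' @seealso \code{\link{alphaDensitySweep}}
#' @export
setClass("SweepResult",
  representation(
    densities = "numeric",
    alphas = "numeric",
    aucLGC = "array",
    aucMVAR = "matrix",
    pooledAucLGC = "matrix",
    pooledAucMVAR = "numeric",
    deltaAucPooled = "matrix",
    deltaAucMedian = "matrix",
    order = "integer",
    seed = "integer"
  )
)

setValidity("SweepResult", function(object) {
  msg <- character()
  ok <- function(v) all(v >= 0 & v <= 1, na.rm = TRUE)
  if (!ok(object@aucLGC) || !ok(object@aucMVAR))
    msg <- c(msg, "all AUCs must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
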