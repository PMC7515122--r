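## Deterministic seeding helpers: every source of randomness in the
## package flows from one master seed through named substreams, so a run
## is reproducible end to end and substreams do not collide across stages.
.streamSalt <- c(network = 101L, noise = 211L, delays = 307L,
                 generic = 401L)

.deriveSeeds <- function(masterSeed, n, stream = "generic") {
  salt <- .streamSalt[[stream]]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(masterSeed) * 7919 + salt) %% 2147483647)
  sample.int(2147483646L, n)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw a random binary directed network at fixed density
#'
#' Samples exactly \code{round(density * L * (L - 1))} off-diagonal
#' positions of an L x L adjacency matrix uniformly without replacement
#' and sets them to 1. \code{A[i, j] = 1} means node j influences node i;
#' the diagonal is zero, and bidirectional pairs and cycles can occur.
#'
#' @param L number of nodes.
#' @param density target edge density in (0, 1].
#' @param seed integer seed making the draw reproducible.
#' @return a \code{\linkS4class{DirectedNetwork}}.
#' @examples
#' net <- randomNetwork(17, 0.0625, seed = 1)
#' nEdges(net)   # 17
#' @export
randomNetwork <- function(L, density, seed) {
  if (density <= 0 || density > 1) stop("'density' must be in (0, 1]")
  ne <- round(density * L * (L - 1))
  if (ne < 1) stop("density ", density, " yields zero edges for L = ", L)
  offDiag <- which(row(matrix(0, L, L)) != col(matrix(0, L, L)))
  picked <- .withSeed(seed, sample(offDiag, ne))
  A <- matrix(0, L, L)
  A[picked] <- 1
  new("DirectedNetwork", adjacency = A, nEdges = as.integer(ne),
      density = density, seed = as.integer(seed))
}

#' The benchmark grid of network densities
#'
#' 19 density values geometrically (log-equidistantly) spaced between
#' 0.01 and 0.5 inclusive.
#'
#' @return strictly increasing numeric vector of length 19.
#' @export
densityGrid <- function() {
  exp(seq(log(0.01), log(0.5), length.out = 19))
}

#' Generate a family of independent random networks
#'
#' Draws \code{count} networks at a common (L, density) with per-network
#' seeds derived deterministically from a master seed.
#'
#' @param L number of nodes.
#' @param density edge density.
#' @param count number of networks (default 32).
#' @param masterSeed integer master seed.
#' @return list of \code{\linkS4class{DirectedNetwork}} objects.
#' @export
networkFamily <- function(L, density, count = 32L, masterSeed = 1L) {
  seeds <- .deriveSeeds(masterSeed, count, "network")
  lapply(seeds, function(s) randomNetwork(L, density, s))
}
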