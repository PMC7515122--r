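#' Read a channels-by-time series matrix from delimited text
#'
#' Expects tab-separated values, one channel per row, optionally preceded
#' by comment lines starting with \code{#} (written by
#' \code{\link{writeSeries}}).
#'
#' @param path file path.
#' @return numeric matrix, channels x time.
#' @export
readSeries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                   comment.char = "#"))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a channels-by-time series matrix as delimited text
#'
#' @param series numeric matrix, channels x time.
#' @param path output file path.
#' @param comments optional character vector written as leading
#'   \code{#} lines (provenance: seed, parameters).
#' @export
writeSeries <- function(series, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines("# channels x time, tab-separated", con)
  utils::write.table(series, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' Write a network as an edge list
#'
#' One \code{source<TAB>target} pair per line, 0-based node indices,
#' with a header comment documenting the convention.
#'
#' @param network a \code{\linkS4class{DirectedNetwork}}.
#' @param path output file path.
#' @export
writeEdgeList <- function(network, path) {
  A <- adjacency(network)
  ij <- which(A == 1, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# source\ttarget (0-based; edge = source influences target)",
               sprintf("%d\t%d", ij[, 2] - 1L, ij[, 1] - 1L)), con)
}

#' Serialize a GCResult as structured text
#'
#' Writes a single JSON document holding the strength, F-ratio, p-value
#' and RSS matrices plus the estimation metadata (p, alpha, basis memory,
#' nObs, m), round-trippable through \code{\link{readGCResult}}.
#'
#' @param result a \code{\linkS4class{GCResult}}.
#' @param path output file path.
#' @export
writeGCResult <- function(result, path) {
  obj <- list(
    order = result@order, alpha = result@alpha, memory = result@memory,
    nObs = result@nObs, m = result@m,
    strengths = result@strengths, fRatios = result@fRatios,
    pValues = result@pValues,
    rssUnrestricted = result@rssUnrestricted,
    rssRestricted = result@rssRestricted)
  jsonlite::write_json(obj, path, digits = NA, na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Read a GCResult written by \code{\link{writeGCResult}}
#'
#' @param path file path.
#' @return a \code{\linkS4class{GCResult}}.
#' @export
readGCResult <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  }
  new("GCResult",
      strengths = toMat(o$strengths), fRatios = toMat(o$fRatios),
      pValues = toMat(o$pValues),
      rssUnrestricted = as.numeric(o$rssUnrestricted),
      rssRestricted = toMat(o$rssRestricted),
      nObs = as.integer(o$nObs), m = as.integer(o$m),
      order = as.integer(o$order), alpha = as.numeric(o$alpha),
      memory = as.integer(o$memory))
}

#' Tidy long-format table of a sweep result
#'
#' Flattens a \code{\linkS4class{SweepResult}} into one row per
#' (density, alpha, network, method) with the AUC, ready for delimited
#' export or plotting.
#'
#' @param sweep a \code{\linkS4class{SweepResult}}.
#' @return data.frame with columns \code{density}, \code{alpha},
#'   \code{network}, \code{method}, \code{auc}.
#' @export
sweepTable <- function(sweep) {
  nd <- length(sweep@densities); na <- length(sweep@alphas)
  nn <- dim(sweep@aucLGC)[3]
  lgc <- expand.grid(density = sweep@densities, alpha = sweep@alphas,
                     network = seq_len(nn))
  lgc$method <- "lgc"
  lgc$auc <- as.vector(sweep@aucLGC)
  mv <- expand.grid(density = sweep@densities, network = seq_len(nn))
  mv$alpha <- 0
  mv$method <- "mvar"
  mv$auc <- as.vector(sweep@aucMVAR)
  out <- rbind(lgc[, c("density", "alpha", "network", "method", "auc")],
               mv[, c("density", "alpha", "network", "method", "auc")])
  out[order(out$density, out$alpha, out$network), ]
}

#' Write a run manifest
#'
#' Records the command, full configuration echo, master seed, package
#' version, stage timings and every output file produced, as JSON, so a
#' deterministic stage can be re-run bit-identically from the manifest
#' alone.
#'
#' @param path output path.
#' @param command character, the command or function that ran.
#' @param config named list echoing the full configuration.
#' @param seed master seed.
#' @param outputs character vector of output file paths.
#' @param timings named numeric vector of per-stage elapsed seconds.
#' @export
writeManifest <- function(path, command, config, seed, outputs,
                          timings = numeric()) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         packageVersion = as.character(utils::packageVersion("laguerreGC")),
         timings = as.list(timings), outputs = outputs,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
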