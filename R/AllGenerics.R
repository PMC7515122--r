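#' @rdname DirectedNetwork-class
#' @param object,x an object.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname DirectedNetwork-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname GCResult-class
#' @export
setGeneric("strengths", function(x) standardGeneric("strengths"))

#' @rdname GCResult-class
#' @export
setGeneric("fRatios", function(x) standardGeneric("fRatios"))

#' @rdname GCResult-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname SimOutput-class
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' @rdname SimOutput-class
#' @export
setGeneric("delays", function(x) standardGeneric("delays"))

#' @rdname SweepResult-class
#' @export
setGeneric("deltaAuc", function(x, ...) standardGeneric("deltaAuc"))

#' @rdname DirectedNetwork-class
setMethod("adjacency", "DirectedNetwork", function(x) x@adjacency)

#' @rdname DirectedNetwork-class
setMethod("nEdges", "DirectedNetwork", function(x) x@nEdges)

#' @rdname GCResult-class
setMethod("strengths", "GCResult", function(x) x@strengths)

#' @rdname GCResult-class
setMethod("fRatios", "GCResult", function(x) x@fRatios)

#' @rdname GCResult-class
setMethod("pValues", "GCResult", function(x) x@pValues)

#' @rdname SimOutput-class
setMethod("seriesMatrix", "SimOutput", function(x) x@x)

#' @rdname SimOutput-class
setMethod("delays", "SimOutput", function(x) x@delays)

#' @rdname SweepResult-class
#' @param aggregation \code{"pooled"} (links pooled across networks before
#'   the ROC) or \code{"median"} (per-network AUCs, then the median).
#' @param ... passed on to methods.
setMethod("deltaAuc", "SweepResult", function(x,
    aggregation = c("pooled", "median")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "pooled") x@deltaAucPooled else x@deltaAucMedian
})

setMethod("show", "LaguerreBasis", function(object) {
  cat("LaguerreBasis: p =", object@orderCount,
      paste0("orders, alpha = ", object@alpha, ","),
      "memory N =", object@memory, "samples\n")
})

setMethod("show", "GCResult", function(object) {
  L <- nrow(object@strengths)
  cat("GCResult:", L, "channels,", L * (L - 1), "ordered pairs\n")
  cat("  order p =", object@order,
      paste0("alpha = ", object@alpha, ","),
      "basis memory N =", object@memory, "\n")
  cat("  nObs =", object@nObs, "m =", object@m, "\n")
  s <- object@strengths[row(object@strengths) != col(object@strengths)]
  cat("  strength range: [", signif(min(s), 4), ",",
      signif(max(s), 4), "]\n")
})

setMethod("show", "DirectedNetwork", function(object) {
  L <- nrow(object@adjacency)
  cat("DirectedNetwork:", L, "nodes,", object@nEdges,
      paste0("edges (density ", signif(object@density, 4), ")\n"))
})

setMethod("show", "SimOutput", function(object) {
  cat("SimOutput:", nrow(object@x), "channels x", ncol(object@x),
      "retained samples (h =", object@config@h, "s)\n")
  cat("  source delays (samples):", paste(object@delays, collapse = " "),
      "\n")
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult:", length(object@densities), "densities x",
      length(object@alphas), "alphas,",
      dim(object@aucLGC)[3], "networks per density\n")
  cat("  max pooled deltaAUC =",
      signif(max(object@deltaAucPooled, na.rm = TRUE), 4), "\n")
})
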