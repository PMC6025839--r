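#' @rdname nbins
#' @export
setMethod("nbins", "BinTable", function(x) length(x@chrom))

#' @rdname nbins
#' @export
setMethod("nbins", "ContactMatrix", function(x) nbins(x@bins))

#' @rdname nbins
#' @export
setMethod("nbins", "HiCGraph", function(x) nbins(x@bins))

#' @rdname resolution
#' @export
setMethod("resolution", "BinTable", function(x) x@resolution)

#' @rdname resolution
#' @export
setMethod("resolution", "ContactMatrix", function(x) x@bins@resolution)

#' @rdname resolution
#' @export
setMethod("resolution", "HiCGraph", function(x) x@resolution)

#' @rdname resolution
#' @export
setMethod("resolution", "SyntheticSpec", function(x) x@resolution)

#' @rdname binTable
#' @export
setMethod("binTable", "ContactMatrix", function(x) x@bins)

#' @rdname binTable
#' @export
setMethod("binTable", "HiCGraph", function(x) x@bins)

#' @rdname binTable
#' @export
setMethod("binTable", "SyntheticSpec", function(x)
  generateBins(x@chromSizes, x@resolution))

#' @rdname binChrom
#' @export
setMethod("binChrom", "BinTable", function(x) x@chrom)

#' @rdname binStart
#' @export
setMethod("binStart", "BinTable", function(x) x@start)

#' @rdname binEnd
#' @export
setMethod("binEnd", "BinTable", function(x) x@end)

#' @rdname binLabels
#' @export
setMethod("binLabels", "BinTable", function(x)
  sprintf("%s:%d-%d", x@chrom, x@start, x@end))

#' @rdname contactValues
#' @export
setMethod("contactValues", "ContactMatrix", function(x) x@values)

#' @rdname edges
#' @export
setMethod("edges", "HiCGraph", function(x) x@edges)

#' @rdname positions
#' @export
setMethod("positions", "LayoutResult", function(x) x@positions)

#' @rdname layoutTrace
#' @export
setMethod("layoutTrace", "LayoutResult", function(x) x@trace)

setMethod("show", "BinTable", function(object) {
  r <- rle(object@chrom)
  cat(sprintf("BinTable: %d bins, %d chromosome(s), resolution %d bp\n",
              nbins(object), length(r$values), object@resolution))
  cat("  ", paste(sprintf("%s (%d bins)", r$values, r$lengths),
                  collapse = ", "), "\n", sep = "")
})

setMethod("show", "ContactMatrix", function(object) {
  v <- object@values
  nz <- sum(v[upper.tri(v)] > 0)
  cat(sprintf(
    "ContactMatrix: %d x %d, %d nonzero upper-triangle entries\n",
    nrow(v), ncol(v), nz))
  show(object@bins)
})

setMethod("show", "HiCGraph", function(object) {
  e <- object@edges
  k <- table(factor(e$kind, levels = c("linear", "cis", "trans")))
  cat(sprintf(
    "HiCGraph: %d vertices; %d linear, %d cis, %d trans edges (resolution %d bp)\n",
    nbins(object), k[["linear"]], k[["cis"]], k[["trans"]],
    object@resolution))
})

setMethod("show", "LayoutResult", function(object) {
  cat(sprintf(
    "LayoutResult: %s layout of %d vertices (seed %d, %d iterations)\n",
    object@algorithm, nrow(object@positions), object@seed,
    length(object@trace)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    paste0("SyntheticSpec: %d chromosome(s) at %d bp resolution\n",
           "  alpha=%g c0=%g transBase=%g territoryStrength=%g ",
           "condensation=%g noiseSd=%g seed=%d\n"),
    length(object@chromSizes), object@resolution, object@alpha, object@c0,
    object@transBase, object@territoryStrength, object@condensation,
    object@noiseSd, object@seed))
})
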