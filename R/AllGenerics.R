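#' Number of genomic bins
#' @param x a [BinTable-class], [ContactMatrix-class] or [HiCGraph-class].
#' @return integer bin count.
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))

#' Bin resolution in bp
#' @param x an object carrying a bin resolution.
#' @return integer resolution (bp).
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))

#' The BinTable of an object
#' @param x a [ContactMatrix-class], [HiCGraph-class] or [SyntheticSpec-class].
#' @return the [BinTable-class].
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' Chromosome of each bin
#' @param x a [BinTable-class].
#' @return character vector, one chromosome name per bin.
#' @export
setGeneric("binChrom", function(x) standardGeneric("binChrom"))

#' 0-based start of each bin
#' @param x a [BinTable-class].
#' @return integer vector (bp).
#' @export
setGeneric("binStart", function(x) standardGeneric("binStart"))

#' Exclusive end of each bin
#' @param x a [BinTable-class].
#' @return integer vector (bp).
#' @export
setGeneric("binEnd", function(x) standardGeneric("binEnd"))

#' Bin labels "chrom:start-end"
#' @param x a [BinTable-class].
#' @return character vector of labels in bin order.
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' Interaction-frequency matrix
#' @param x a [ContactMatrix-class].
#' @return numeric N x N matrix.
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))

#' Edge table of a Hi-C graph
#' @param x a [HiCGraph-class].
#' @return data.frame with columns u, v (0-based), kind, weight,
#'   measured_freq, sorted by kind (linear, cis, trans) then u then v.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Layout coordinates
#' @param x a [LayoutResult-class].
#' @return numeric N x 2 matrix of (x, y) positions in bin order.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Per-iteration diagnostic trace of a layout run
#'
#' For stress layouts this is the (non-increasing) stress objective per
#' majorization sweep; for ForceAtlas2 it is the global swing per step.
#' @param x a [LayoutResult-class].
#' @return numeric vector.
#' @export
setGeneric("layoutTrace", function(x) standardGeneric("layoutTrace"))
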