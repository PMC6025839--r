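#' @import methods
NULL

#' BinTable: ordered genomic bins at fixed resolution
#'
#' An ordered partition of a genome into fixed-width bins. Coordinates are
#' 0-based, half-open \code{[start, end)} (BED convention). The 0-based
#' global bin index (row order) is the vertex identity used by every
#' downstream structure: contact matrices, graphs, layouts and file formats
#' all refer to bins by this index.
#'
#' Invariants enforced by the validity method: bins are grouped by
#' chromosome and sorted by start; intervals are contiguous and
#' non-overlapping within a chromosome; every bin has width at most
#' \code{resolution}, and exactly \code{resolution} except possibly the last
#' bin of each chromosome (truncated at the chromosome end).
#'
#' @slot chrom character vector, chromosome of each bin.
#' @slot start integer vector, 0-based inclusive start of each bin (bp).
#' @slot end integer vector, exclusive end of each bin (bp).
#' @slot resolution integer, nominal bin width in bp.
#'
#' @seealso [generateBins()], [readBinTable()]
#' @export
setClass("BinTable",
  slots = c(
    chrom = "character",
    start = "integer",
    end = "integer",
    resolution = "integer"
  )
)

setValidity("BinTable", function(object) {
  n <- length(object@chrom)
  if (length(object@start) != n || length(object@end) != n)
    return("chrom, start and end must have equal length")
  if (length(object@resolution) != 1L || is.na(object@resolution) ||
      object@resolution <= 0L)
    return("resolution must be a single positive integer")
  if (n == 0L) return(TRUE)
  if (anyNA(object@start) || anyNA(object@end) || anyNA(object@chrom))
    return("bin fields must not contain NA")
  if (any(object@start < 0L)) return("starts must be non-negative")
  w <- object@end - object@start
  if (any(w <= 0L)) return("every bin must have positive width")
  if (any(w > object@resolution))
    return("bin width exceeds resolution")
  # chromosomes must form contiguous blocks
  r <- rle(object@chrom)
  if (anyDuplicated(r$values))
    return("bins of one chromosome must be contiguous in the table")
  idx <- cumsum(r$lengths)          # last bin of each chromosome
  first <- c(1L, head(idx, -1L) + 1L)
  # contiguity within chromosome
  within <- setdiff(seq_len(n), first)
  if (length(within) &&
      any(object@start[within] != object@end[within - 1L]))
    return("bins must be contiguous within each chromosome")
  # only the last bin of a chromosome may be short
  short <- which(w < object@resolution)
  if (length(setdiff(short, idx)))
    return("only the last bin of a chromosome may be shorter than resolution")
  TRUE
})

#' ContactMatrix: a symmetric Hi-C interaction-frequency matrix
#'
#' A dense symmetric N x N matrix of non-negative interaction frequencies
#' tied to a [BinTable-class] with N bins. Entry (i, j) records the
#' (normalized) interaction frequency between genomic bins i and j.
#' Diagonal entries are stored but ignored by graph construction.
#'
#' @slot values numeric N x N matrix, symmetric, non-negative.
#' @slot bins the [BinTable-class] defining bin identity.
#'
#' @seealso [readContactMap()], [simulateContactMap()], [buildGraph()]
#' @export
setClass("ContactMatrix",
  slots = c(values = "matrix", bins = "BinTable")
)

setValidity("ContactMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != ncol(v)) return("values must be square")
  if (nrow(v) != nbins(object@bins))
    return("matrix dimension must equal the number of bins")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("values must be non-negative")
  if (!isSymmetric(unname(v), tol = 1e-9))
    return("values must be symmetric (tolerance 1e-9)")
  TRUE
})

#' HiCGraph: the undirected weighted graph of a contact map
#'
#' The central object of the package: one vertex per genomic bin and three
#' kinds of undirected weighted edges.
#' \itemize{
#'   \item \code{linear} - the chromosome backbone: one edge between each
#'     pair of bins that are adjacent on the same chromosome, weighted
#'     exactly \code{1/resolution}. When the contact map also reports an
#'     interaction between those two bins, its frequency is carried in the
#'     \code{measured_freq} column of the edge table (the backbone weight
#'     itself is never altered).
#'   \item \code{cis} - a measured interaction between two non-adjacent
#'     bins of the same chromosome, weighted by its frequency.
#'   \item \code{trans} - a measured interaction between bins of different
#'     chromosomes, weighted by its frequency.
#' }
#' Edge endpoints are 0-based global bin indices with \code{u < v}; each
#' unordered pair carries at most one edge per kind. The edge table is kept
#' sorted by kind (linear, cis, trans), then \code{u}, then \code{v}, so
#' writers are deterministic.
#'
#' @slot bins the [BinTable-class] (vertex set).
#' @slot edges data.frame with columns \code{u}, \code{v} (integer, 0-based),
#'   \code{kind} (character), \code{weight} (numeric) and
#'   \code{measured_freq} (numeric, \code{NA} where no interaction was
#'   measured on a backbone edge).
#' @slot resolution integer bp.
#'
#' @seealso [buildGraph()], [edges()], [stressLayout()], [forceAtlas2()]
#' @export
setClass("HiCGraph",
  slots = c(bins = "BinTable", edges = "data.frame", resolution = "integer")
)

setValidity("HiCGraph", function(object) {
  e <- object@edges
  need <- c("u", "v", "kind", "weight", "measured_freq")
  if (!all(need %in% names(e))) return("edge table missing required columns")
  if (nrow(e) == 0L) return(TRUE)
  n <- nbins(object@bins)
  if (any(e$u < 0L) || any(e$v >= n)) return("edge endpoint out of range")
  if (any(e$u >= e$v)) return("edges must satisfy u < v (no self-loops)")
  if (!all(e$kind %in% c("linear", "cis", "trans")))
    return("edge kind must be linear, cis or trans")
  if (any(e$weight < 0)) return("edge weights must be non-negative")
  if (anyDuplicated(e[, c("u", "v", "kind")]))
    return("duplicate edge for an unordered pair and kind")
  lin <- e$kind == "linear"
  if (any(abs(e$weight[lin] - 1 / object@resolution) > 0))
    return("linear edges must have weight exactly 1/resolution")
  TRUE
})

#' LayoutResult: 2D coordinates from a force-directed layout
#'
#' @slot positions numeric N x 2 matrix of (x, y) coordinates, one row per
#'   bin in global index order; rownames are bin labels.
#' @slot trace numeric vector of per-iteration diagnostics: the stress value
#'   for \code{algorithm = "stress"} (non-increasing by construction), the
#'   global swing for \code{algorithm = "forceatlas2"}.
#' @slot seed integer seed the layout was started from.
#' @slot algorithm character, \code{"stress"} or \code{"forceatlas2"}.
#' @slot params list of the algorithm parameters actually used.
#'
#' @seealso [stressLayout()], [forceAtlas2()], [renderLayout()]
#' @export
setClass("LayoutResult",
  slots = c(
    positions = "matrix",
    trace = "numeric",
    seed = "integer",
    algorithm = "character",
    params = "list"
  )
)

setValidity("LayoutResult", function(object) {
  p <- object@positions
  if (ncol(p) != 2L) return("positions must have two columns")
  if (anyNA(p) || any(!is.finite(p))) return("coordinates must be finite")
  if (!object@algorithm %in% c("stress", "forceatlas2"))
    return("algorithm must be 'stress' or 'forceatlas2'")
  TRUE
})

#' SyntheticSpec: parameters of a simulated contact map
#'
#' Describes a synthetic normalized contact map with power-law distance
#' decay along chromosomes, chromosome-territory structure, a condensation
#' parameter trading cis against trans contacts, and multiplicative
#' lognormal noise. See [simulateContactMap()] for the generative model.
#'
#' @slot chromSizes named numeric vector of chromosome lengths (bp).
#' @slot resolution integer bin width (bp).
#' @slot alpha decay exponent (> 0) of cis frequency with bin separation.
#' @slot c0 cis contact scale (> 0): expected frequency of adjacent bins
#'   before condensation.
#' @slot transBase baseline trans frequency (>= 0).
#' @slot territoryStrength in [0, 1]; multiplies trans frequencies by
#'   \code{1 - territoryStrength} (1 = perfect territories, no trans).
#' @slot condensation >= 0; boosts cis by \code{1 + condensation} and damps
#'   trans by \code{1/(1 + condensation)} (mitotic-like compaction).
#' @slot noiseSd lognormal sigma (>= 0) of multiplicative noise.
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticSpec()], [syntheticPreset()], [simulateContactMap()]
#' @export
setClass("SyntheticSpec",
  slots = c(
    chromSizes = "numeric",
    resolution = "integer",
    alpha = "numeric",
    c0 = "numeric",
    transBase = "numeric",
    territoryStrength = "numeric",
    condensation = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (length(object@chromSizes) == 0L || is.null(names(object@chromSizes)))
    return("chromSizes must be a named vector")
  if (any(object@chromSizes <= 0)) return("chromosome lengths must be positive")
  if (object@resolution <= 0L) return("resolution must be positive")
  if (object@alpha <= 0) return("alpha must be > 0")
  if (object@c0 <= 0) return("c0 must be > 0")
  if (object@transBase < 0) return("transBase must be >= 0")
  if (object@territoryStrength < 0 || object@territoryStrength > 1)
    return("territoryStrength must be in [0, 1]")
  if (object@condensation < 0) return("condensation must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})
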