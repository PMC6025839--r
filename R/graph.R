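#' Classify a bin pair as a linear, cis or trans interaction
#'
#' Two bins on different chromosomes interact in \code{trans}; bins on the
#' same chromosome are \code{linear} neighbours when they are adjacent
#' along the chromosome (consecutive global indices) and \code{cis}
#' otherwise. Vectorized over pairs.
#'
#' @param bins a [BinTable-class].
#' @param u,v 0-based global bin indices (equal-length vectors); u != v.
#' @return character vector in \code{c("linear", "cis", "trans")}.
#' @examples
#' b <- generateBins(c(chrI = 50000, chrII = 30000), 10000)
#' classifyPair(b, c(3, 3, 3), c(4, 1, 6))  # linear, cis, trans
#' @export
classifyPair <- function(bins, u, v) {
  stopifnot(is(bins, "BinTable"), length(u) == length(v))
  n <- nbins(bins)
  if (any(u < 0L | u >= n | v < 0L | v >= n))
    stopf("bin index out of range 0..%d", n - 1L)
  if (any(u == v)) stopf("cannot classify a bin against itself")
  cu <- bins@chrom[u + 1L]
  cv <- bins@chrom[v + 1L]
  out <- ifelse(cu != cv, "trans",
                ifelse(abs(u - v) == 1L, "linear", "cis"))
  out
}

#' Build the Hi-C interaction graph from a contact map
#'
#' Constructs the central graph object: every genomic bin becomes a vertex
#' (bins with no reported interactions keep their backbone edges only),
#' every pair of bins adjacent on the same chromosome is joined by a
#' \code{linear} backbone edge of weight exactly \code{1/resolution}, and
#' every upper-triangle contact-map entry whose (optionally scaled)
#' frequency \code{f = scale * values[i, j]} exceeds \code{minFreq} becomes
#' a \code{cis} or \code{trans} edge of weight \code{f}. A measured
#' frequency between backbone-adjacent bins does not create a second edge:
#' it is stored in the \code{measured_freq} column of the linear edge, and
#' layouts may combine it with the backbone weight (see
#' [effectiveWeights()]). Diagonal entries are ignored. The number of
#' linear edges is always \code{N - C} for N bins on C chromosomes.
#'
#' @param matrix a [ContactMatrix-class].
#' @param resolution integer bp; must equal the bin-table resolution
#'   (defaults to it).
#' @param minFreq non-negative threshold; only scaled frequencies strictly
#'   greater than this become interaction edges (default 0: all positive
#'   entries are kept).
#' @param scale positive multiplicative scaling of frequencies (default 1,
#'   no scaling).
#' @return a [HiCGraph-class].
#' @examples
#' b <- generateBins(c(chrI = 30000), 10000)
#' m <- matrix(0, 3, 3); m[1, 3] <- m[3, 1] <- 0.5
#' g <- buildGraph(ContactMatrix(m, b))
#' edges(g)
#' @export
buildGraph <- function(matrix, resolution = NULL, minFreq = 0, scale = 1) {
  stopifnot(is(matrix, "ContactMatrix"))
  bins <- matrix@bins
  if (is.null(resolution)) resolution <- bins@resolution
  if (length(resolution) != 1L || resolution <= 0)
    stopf("resolution must be a single positive integer")
  if (as.integer(resolution) != bins@resolution)
    stopf("resolution %d does not match the bin table (%d)",
          as.integer(resolution), bins@resolution)
  if (minFreq < 0) stopf("minFreq must be >= 0")
  if (scale <= 0) stopf("scale factor must be a single positive number")
  resolution <- as.integer(resolution)
  n <- nbins(bins)
  code <- chromCode(bins)

  # backbone: consecutive global indices on the same chromosome
  lin_u <- which(code[-n] == code[-1L])            # 1-based left endpoint
  linear <- data.frame(
    u = lin_u - 1L, v = lin_u,
    kind = rep.int("linear", length(lin_u)),
    weight = rep.int(1 / resolution, length(lin_u)),
    measured_freq = rep.int(NA_real_, length(lin_u)),
    stringsAsFactors = FALSE)

  f <- matrix@values * scale
  idx <- which(upper.tri(f) & f > minFreq, arr.ind = TRUE)
  iu <- idx[, 1] - 1L                               # 0-based
  iv <- idx[, 2] - 1L
  same <- code[idx[, 1]] == code[idx[, 2]]
  adjacent <- same & (iv - iu == 1L)
  fw <- f[idx]

  if (any(adjacent)) {
    pos <- match(iu[adjacent], linear$u)
    linear$measured_freq[pos] <- fw[adjacent]
  }
  keep <- !adjacent
  inter <- data.frame(
    u = iu[keep], v = iv[keep],
    kind = ifelse(same[keep], "cis", "trans"),
    weight = fw[keep],
    measured_freq = rep.int(NA_real_, sum(keep)),
    stringsAsFactors = FALSE)

  e <- rbind(linear, inter)
  e <- e[order(factor(e$kind, levels = c("linear", "cis", "trans")),
               e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  new("HiCGraph", bins = bins, edges = e, resolution = resolution)
}

#' Effective edge weights under a combination rule
#'
#' The backbone edge between adjacent bins has structural weight
#' \code{1/resolution} and may additionally carry a measured interaction
#' frequency. Layouts and the adjacency exporter combine the two:
#' \describe{
#'   \item{sum}{linear edges weigh \code{1/resolution + measured_freq}
#'     (0 when nothing was measured); cis/trans edges keep their
#'     frequency. Default: backbone and measured contact both attract.}
#'   \item{interaction_only}{linear edges weigh their measured frequency
#'     when one exists, else \code{1/resolution}; cis/trans unchanged.}
#' }
#'
#' @param graph a [HiCGraph-class].
#' @param combine \code{"sum"} or \code{"interaction_only"}.
#' @return numeric vector of weights aligned with \code{edges(graph)} rows.
#' @export
effectiveWeights <- function(graph, combine = c("sum", "interaction_only")) {
  combine <- match.arg(combine)
  e <- graph@edges
  w <- e$weight
  lin <- e$kind == "linear"
  mf <- e$measured_freq
  if (combine == "sum") {
    w[lin] <- w[lin] + ifelse(is.na(mf[lin]), 0, mf[lin])
  } else {
    w[lin] <- ifelse(is.na(mf[lin]), w[lin], mf[lin])
  }
  w
}

# igraph view of a HiCGraph (vertices 1..N; weight attribute = effective
# weights). Internal: layouts and component handling.
asIgraph <- function(graph, combine = "sum") {
  e <- graph@edges
  g <- igraph::make_empty_graph(n = nbins(graph), directed = FALSE)
  if (nrow(e))
    g <- igraph::add_edges(g, rbind(e$u + 1L, e$v + 1L))
  igraph::E(g)$weight <- effectiveWeights(graph, combine)
  g
}
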