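#' Ratio of total cis to total trans edge weight
#'
#' Sums the interaction-frequency weights of all cis edges and divides by
#' the corresponding trans sum. Chromosome condensation (e.g. during
#' mitosis) raises cis contacts and depletes trans contacts, so a larger
#' ratio indicates a more condensed, more territorial organization. The
#' value is invariant to a multiplicative rescaling of frequencies (the
#' factor cancels). Returns \code{Inf} when there are cis but no trans
#' edges and \code{NaN} when there are neither — the undefined cases are
#' flagged by those IEEE values rather than an error.
#'
#' @param graph a [HiCGraph-class].
#' @return non-negative number, \code{Inf}, or \code{NaN}.
#' @export
cisTransRatio <- function(graph) {
  stopifnot(is(graph, "HiCGraph"))
  e <- graph@edges
  cis <- sum(e$weight[e$kind == "cis"])
  trans <- sum(e$weight[e$kind == "trans"])
  if (trans == 0) {
    if (cis > 0) return(Inf)
    return(NaN)
  }
  cis / trans
}

#' Chromosome intermingling in a layout (k-nearest-neighbour mixing)
#'
#' For every vertex, the fraction of its k nearest neighbours in the
#' layout (Euclidean distance, ties broken by lower bin index) that lie on
#' a different chromosome; the statistic is the mean over vertices. 0
#' means perfectly separated chromosomes, values near 1 mean thorough
#' visual intermingling (e.g. a cohesin-mutant-like loss of territories).
#' Invariant to rigid motions and uniform scaling of the coordinates.
#'
#' @param layout a [LayoutResult-class].
#' @param bins the matching [BinTable-class].
#' @param k number of neighbours, \code{1 <= k < N} (default 10, a local
#'   neighbourhood at the ~1258-bin scale).
#' @return number in [0, 1].
#' @export
neighborhoodMixing <- function(layout, bins, k = 10L) {
  stopifnot(is(layout, "LayoutResult"), is(bins, "BinTable"))
  pos <- layout@positions
  n <- nrow(pos)
  if (n != nbins(bins))
    stopf("layout has %d positions but the bin table has %d bins",
          n, nbins(bins))
  if (k < 1L || k >= n) stopf("k must satisfy 1 <= k < %d", n)
  code <- chromCode(bins)
  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf
  other <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k)]  # ties: lower bin index
    sum(code[nb] != code[i]) / k
  }, numeric(1))
  mean(other)
}

#' Chromosome-territory separation of a layout
#'
#' Ratio of the mean pairwise distance between chromosome centroids to
#' the mean within-chromosome root-mean-square spread around those
#' centroids. Larger values mean chromosomes occupy more distinct regions
#' of the layout (territorial organization); the statistic is invariant to
#' rigid motions and uniform scaling.
#'
#' @param layout a [LayoutResult-class].
#' @param bins the matching [BinTable-class]; needs >= 2 chromosomes.
#' @return positive number (possibly \code{Inf} for degenerate
#'   zero-spread clusters).
#' @export
territorySeparation <- function(layout, bins) {
  stopifnot(is(layout, "LayoutResult"), is(bins, "BinTable"))
  pos <- layout@positions
  if (nrow(pos) != nbins(bins))
    stopf("layout has %d positions but the bin table has %d bins",
          nrow(pos), nbins(bins))
  code <- chromCode(bins)
  C <- max(code)
  if (C < 2L) stopf("territory separation needs at least 2 chromosomes")
  cx <- tapply(pos[, 1], code, mean)
  cy <- tapply(pos[, 2], code, mean)
  cent <- cbind(cx, cy)
  dcent <- stats::dist(cent)
  spread <- vapply(seq_len(C), function(ci) {
    p <- pos[code == ci, , drop = FALSE]
    sqrt(mean((p[, 1] - cx[ci])^2 + (p[, 2] - cy[ci])^2))
  }, numeric(1))
  mean(dcent) / mean(spread)
}
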