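#' Construct a ContactMatrix
#'
#' Validates symmetry (tolerance 1e-9, reporting the first offending pair
#' in 0-based indices), non-negativity and the dimension against the bin
#' table, then symmetrizes exactly so downstream arithmetic is clean.
#'
#' @param values numeric N x N matrix of interaction frequencies.
#' @param bins a [BinTable-class] with N bins.
#' @return a [ContactMatrix-class].
#' @export
ContactMatrix <- function(values, bins) {
  stopifnot(is(bins, "BinTable"))
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("contact map values must be numeric")
  n <- nbins(bins)
  if (nrow(values) != n || ncol(values) != n)
    stopf("contact map is %d x %d but the bin table has %d bins",
          nrow(values), ncol(values), n)
  if (anyNA(values) || any(!is.finite(values)))
    stopf("contact map contains missing or non-finite values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative frequency at (%d, %d)", neg[1, 1] - 1L, neg[1, 2] - 1L)
  asym <- which(abs(values - t(values)) > 1e-9, arr.ind = TRUE)
  if (nrow(asym)) {
    bad <- asym[asym[, 1] < asym[, 2], , drop = FALSE]
    stopf("contact map not symmetric at (%d, %d): %g vs %g",
          bad[1, 1] - 1L, bad[1, 2] - 1L,
          values[bad[1, 1], bad[1, 2]], values[bad[1, 2], bad[1, 1]])
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  new("ContactMatrix", values = values, bins = bins)
}

#' Read a contact map from a dense or triplet text file
#'
#' Two plain-text formats are supported:
#' \describe{
#'   \item{dense}{whitespace/tab-delimited N x N numeric matrix, no
#'     header. Must be symmetric within 1e-9; the first offending (i, j)
#'     pair (0-based) is named on error.}
#'   \item{triplet}{TSV lines \code{bin_i bin_j frequency} with 0-based
#'     bin indices by default (\code{oneBased = TRUE} for files indexed
#'     from 1, common in GEO dumps). Lines starting with \code{#} are
#'     ignored. Each entry is mirrored to enforce symmetry; absent pairs
#'     are 0; conflicting duplicate entries are an error.}
#' }
#'
#' @param path file path.
#' @param format \code{"dense"} or \code{"triplet"}.
#' @param bins the [BinTable-class] the map must conform to.
#' @param oneBased logical; triplet indices start at 1 instead of 0.
#' @return a [ContactMatrix-class].
#' @export
readContactMap <- function(path, format = c("dense", "triplet"), bins,
                           oneBased = FALSE) {
  format <- match.arg(format)
  stopifnot(is(bins, "BinTable"))
  n <- nbins(bins)
  if (format == "dense") {
    d <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "numeric")
    if (nrow(d) != n || ncol(d) != n)
      stopf("dense map is %d x %d but the bin table has %d bins",
            nrow(d), ncol(d), n)
    return(ContactMatrix(as.matrix(d), bins))
  }
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("i", "j", "freq"),
                         colClasses = c("integer", "integer", "numeric"))
  if (oneBased) {
    d$i <- d$i - 1L
    d$j <- d$j - 1L
  }
  if (nrow(d) && (min(d$i, d$j) < 0L || max(d$i, d$j) >= n))
    stopf("triplet bin index out of range 0..%d (is the file one-based?)",
          n - 1L)
  if (any(d$freq < 0))
    stopf("negative frequency at (%d, %d)",
          d$i[d$freq < 0][1], d$j[d$freq < 0][1])
  m <- matrix(0, n, n)
  # mirror each triplet; detect conflicting duplicates for the same pair
  lo <- pmin(d$i, d$j)
  hi <- pmax(d$i, d$j)
  key <- lo * n + hi
  if (anyDuplicated(key)) {
    split_freq <- split(d$freq, key)
    bad <- vapply(split_freq, function(f) diff(range(f)) > 1e-9, logical(1))
    if (any(bad)) {
      k <- as.numeric(names(split_freq)[bad][1])
      stopf("conflicting duplicate triplet entries for pair (%d, %d)",
            k %/% n, k %% n)
    }
  }
  m[cbind(lo + 1L, hi + 1L)] <- d$freq
  m[cbind(hi + 1L, lo + 1L)] <- d$freq
  ContactMatrix(m, bins)
}

#' Write a contact map as dense or triplet text
#'
#' Dense output is the full symmetric matrix (N rows of N fields); triplet
#' output lists only nonzero entries of the upper triangle (including the
#' diagonal), 0-based. Numbers are written in shortest round-trip form, so
#' \code{readContactMap(writeContactMap(m))} reproduces \code{m} exactly
#' and identical matrices give byte-identical files.
#'
#' @param matrix a [ContactMatrix-class].
#' @param path output file path.
#' @param format \code{"dense"} or \code{"triplet"}.
#' @return invisibly, \code{path}.
#' @export
writeContactMap <- function(matrix, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  stopifnot(is(matrix, "ContactMatrix"))
  v <- matrix@values
  if (format == "dense") {
    lines <- apply(v, 1L, function(row) paste(fmtNum(row), collapse = "\t"))
    writeLines(lines, path)
    return(invisible(path))
  }
  idx <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                   fmtNum(v[idx]))
  writeLines(lines, path)
  invisible(path)
}

#' Iterative correction (matrix balancing) of a raw contact map
#'
#' Convenience for raw (unnormalized) maps; the graph model itself expects
#' already-normalized input and balancing is never applied automatically.
#' Implements the symmetric iterative-correction update: at each sweep the
#' off-diagonal marginal sum s_i of every unmasked bin is computed, each
#' entry is divided by \code{(s_i/s̄)(s_j/s̄)} with \code{s̄} the mean
#' nonzero marginal, and the sweep repeats until the coefficient of
#' variation of the nonzero marginals falls below \code{tolerance} or
#' \code{maxIter} is reached. Bins whose off-diagonal row is entirely zero
#' (unmappable regions) are masked and returned unchanged; the zero
#' pattern and symmetry are preserved. The result is rescaled so that the
#' mean nonzero entry is at most 1 (fractional frequencies).
#'
#' @param matrix a [ContactMatrix-class] of raw counts or frequencies.
#' @param tolerance positive convergence threshold on the CV of marginals.
#' @param maxIter maximum number of sweeps.
#' @return a balanced [ContactMatrix-class].
#' @export
iterativeBalance <- function(matrix, tolerance = 1e-5, maxIter = 200L) {
  stopifnot(is(matrix, "ContactMatrix"))
  if (tolerance <= 0) stopf("tolerance must be > 0")
  v <- matrix@values
  diag_save <- diag(v)
  diag(v) <- 0
  if (all(v == 0)) stopf("empty contact map")
  mask <- rowSums(v) == 0            # unmappable bins: leave untouched
  act <- !mask
  for (iter in seq_len(maxIter)) {
    s <- rowSums(v)[act]
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv) || cv < tolerance) break
    b <- s / mean(s)
    v[act, act] <- v[act, act] / outer(b, b)
  }
  nz <- v[v > 0]
  scale <- max(1, mean(nz))
  v <- v / scale
  diag(v) <- diag_save / scale
  ContactMatrix(v, matrix@bins)
}

#' Scale all interaction frequencies by a constant
#'
#' Multiplies every entry by \code{factor} (> 0); symmetry and the zero
#' pattern are preserved. Mirrors the optional linear scaling step offered
#' before graph construction.
#'
#' @param matrix a [ContactMatrix-class].
#' @param factor positive scale factor.
#' @return a [ContactMatrix-class].
#' @export
scaleFrequencies <- function(matrix, factor) {
  stopifnot(is(matrix, "ContactMatrix"))
  if (length(factor) != 1L || is.na(factor) || factor <= 0)
    stopf("scale factor must be a single positive number")
  new("ContactMatrix", values = matrix@values * factor, bins = matrix@bins)
}
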