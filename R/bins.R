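#' Construct a BinTable from explicit intervals
#'
#' Low-level constructor; most users call [generateBins()] instead.
#'
#' @param chrom character vector of chromosome names, grouped.
#' @param start integer vector of 0-based starts (bp).
#' @param end integer vector of exclusive ends (bp).
#' @param resolution integer nominal bin width (bp).
#' @return a validated [BinTable-class].
#' @export
BinTable <- function(chrom, start, end, resolution) {
  new("BinTable",
      chrom = as.character(chrom),
      start = as.integer(start),
      end = as.integer(end),
      resolution = as.integer(resolution))
}

#' Partition chromosomes into fixed-width genomic bins
#'
#' Each chromosome of length L is split into \code{ceiling(L/resolution)}
#' consecutive bins of width \code{resolution}; the last bin of a
#' chromosome is truncated at the chromosome end. Intervals are 0-based,
#' half-open. Bin order (chromosome input order, then position) defines the
#' global 0-based bin index used everywhere downstream. For example, the
#' three fission-yeast chromosomes (5,579,133 / 4,539,804 / 2,452,883 bp)
#' at 10 kb resolution yield 1258 bins.
#'
#' @param chromSizes named numeric vector of chromosome lengths in bp;
#'   names are chromosome names, order is preserved.
#' @param resolution integer bin width in bp (> 0).
#' @return a [BinTable-class].
#' @examples
#' generateBins(c(I = 5579133, II = 4539804, III = 2452883), 10000)
#' @export
generateBins <- function(chromSizes, resolution) {
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0)
    stopf("resolution must be a single positive integer")
  if (length(chromSizes) == 0L)
    stopf("chromSizes must contain at least one chromosome")
  if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
    stopf("chromSizes must be named by chromosome")
  if (anyNA(chromSizes) || any(chromSizes <= 0))
    stopf("all chromosome lengths must be positive")
  resolution <- as.integer(resolution)
  pieces <- lapply(seq_along(chromSizes), function(i) {
    len <- as.integer(chromSizes[[i]])
    k <- as.integer(ceiling(len / resolution))
    start <- (seq_len(k) - 1L) * resolution
    end <- pmin(start + resolution, len)
    list(chrom = rep.int(names(chromSizes)[i], k), start = start, end = end)
  })
  BinTable(
    chrom = unlist(lapply(pieces, `[[`, "chrom")),
    start = unlist(lapply(pieces, `[[`, "start")),
    end = unlist(lapply(pieces, `[[`, "end")),
    resolution = resolution)
}

#' Read a bin table from a BED3-like TSV
#'
#' Expects three tab/whitespace-separated columns \code{chrom start end}
#' in bin order, no header, 0-based half-open coordinates; lines starting
#' with \code{#} are ignored.
#'
#' @param path file path.
#' @param resolution integer bp; if \code{NULL}, inferred as the maximum
#'   bin width in the file.
#' @return a [BinTable-class].
#' @export
readBinTable <- function(path, resolution = NULL) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  if (nrow(d) == 0L) stopf("empty bin table: %s", path)
  if (is.null(resolution)) resolution <- max(d$end - d$start)
  BinTable(d$chrom, d$start, d$end, resolution)
}

#' Write a bin table as BED3 TSV
#'
#' @param bins a [BinTable-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeBinTable <- function(bins, path) {
  stopifnot(is(bins, "BinTable"))
  lines <- sprintf("%s\t%d\t%d", bins@chrom, bins@start, bins@end)
  writeLines(lines, path)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#'
#' Columns \code{chrom length}; comment lines starting with \code{#}
#' ignored.
#'
#' @param path file path.
#' @return named numeric vector of lengths in file order.
#' @export
readChromSizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  if (nrow(d) == 0L) stopf("empty chromosome-sizes file: %s", path)
  stats::setNames(d$length, d$chrom)
}
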