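#' Write a graph as a TSV edge list for Cytoscape/Gephi
#'
#' Columns \code{source target kind weight} with header; vertices are
#' labelled \code{chrom:start-end}; one row per edge in deterministic
#' order (kind: linear, cis, trans; then u; then v). Identical graphs
#' produce byte-identical files. Note the fixed four-column layout means a
#' measured frequency carried on a backbone edge is not written here (the
#' backbone weight 1/resolution is); use [writeAdjacency()] with
#' \code{combine = "sum"} when that matters.
#'
#' @param graph a [HiCGraph-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(is(graph, "HiCGraph"))
  lab <- binLabels(graph@bins)
  e <- graph@edges
  lines <- c("source\ttarget\tkind\tweight",
             sprintf("%s\t%s\t%s\t%s",
                     lab[e$u + 1L], lab[e$v + 1L], e$kind, fmtNum(e$weight)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph back from an edge-list TSV
#'
#' Inverse of [writeEdgeList()] for the CLI workflow. The vertex set is
#' taken from \code{bins} when given; otherwise it is reconstructed from
#' the labels appearing in the file (so isolated vertices of single-bin
#' chromosomes would be lost — pass \code{bins} for authoritative
#' identity). Resolution is taken from \code{bins} or inferred as
#' \code{1/weight} of the linear edges.
#'
#' @param path edge-list file written by [writeEdgeList()].
#' @param bins optional [BinTable-class] giving the vertex set.
#' @return a [HiCGraph-class].
#' @export
readEdgeList <- function(path, bins = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character",
                                        "character", "numeric"))
  parseLab <- function(x) {
    m <- regmatches(x, regexec("^(.*):([0-9]+)-([0-9]+)$", x))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) stopf("malformed vertex label: %s", x[bad][1])
    data.frame(chrom = vapply(m, `[`, "", 2L),
               start = as.integer(vapply(m, `[`, "", 3L)),
               end = as.integer(vapply(m, `[`, "", 4L)),
               stringsAsFactors = FALSE)
  }
  if (is.null(bins)) {
    all_lab <- unique(c(d$source, d$target))
    p <- parseLab(all_lab)
    ord <- order(match(p$chrom, unique(p$chrom)), p$start)
    p <- p[ord, ]
    lin <- d$kind == "linear"
    res <- if (any(lin)) as.integer(round(1 / d$weight[lin][1]))
           else max(p$end - p$start)
    bins <- BinTable(p$chrom, p$start, p$end, res)
  }
  lab <- binLabels(bins)
  u <- match(d$source, lab) - 1L
  v <- match(d$target, lab) - 1L
  if (anyNA(u) || anyNA(v))
    stopf("edge-list vertex label not present in the bin table")
  lo <- pmin(u, v)
  hi <- pmax(u, v)
  e <- data.frame(u = lo, v = hi, kind = d$kind, weight = d$weight,
                  measured_freq = NA_real_, stringsAsFactors = FALSE)
  e <- e[order(factor(e$kind, levels = c("linear", "cis", "trans")),
               e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  new("HiCGraph", bins = bins, edges = e,
      resolution = bins@resolution)
}

#' Combined adjacency matrix of a graph
#'
#' Dense symmetric N x N matrix with zero diagonal; entry (i, j) is the
#' combined weight of the edge between bins i and j under the rule of
#' [effectiveWeights()] (0 where no edge exists).
#'
#' @param graph a [HiCGraph-class].
#' @param combine \code{"sum"} or \code{"interaction_only"}.
#' @return numeric matrix.
#' @export
asAdjacency <- function(graph, combine = c("sum", "interaction_only")) {
  combine <- match.arg(combine)
  n <- nbins(graph)
  e <- graph@edges
  w <- effectiveWeights(graph, combine)
  m <- matrix(0, n, n)
  m[cbind(e$u + 1L, e$v + 1L)] <- w
  m[cbind(e$v + 1L, e$u + 1L)] <- w
  m
}

#' Write the combined adjacency matrix as dense text
#'
#' The dense whitespace-delimited adjacency-matrix intermediate of the
#' visualization workflow: symmetric, zero diagonal, combined edge weights
#' per [asAdjacency()]. Deterministic (shortest round-trip number
#' formatting).
#'
#' @param graph a [HiCGraph-class].
#' @param path output file path.
#' @param combine \code{"sum"} or \code{"interaction_only"}.
#' @return invisibly, \code{path}.
#' @export
writeAdjacency <- function(graph, path,
                           combine = c("sum", "interaction_only")) {
  m <- asAdjacency(graph, combine)
  lines <- apply(m, 1L, function(row) paste(fmtNum(row), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a graph as GraphML or GEXF XML
#'
#' Produces well-formed XML directly importable by Cytoscape (GraphML) or
#' Gephi (GEXF 1.2). Vertices carry \code{chrom}, \code{start}, \code{end}
#' attributes; edges carry \code{kind} and \code{weight}; the edge mode is
#' declared undirected. Output is deterministic.
#'
#' @param graph a [HiCGraph-class].
#' @param path output file path.
#' @param dialect \code{"graphml"} or \code{"gexf"}.
#' @return invisibly, \code{path}.
#' @export
writeGraphXML <- function(graph, path, dialect = c("graphml", "gexf")) {
  dialect <- match.arg(dialect)
  stopifnot(is(graph, "HiCGraph"))
  b <- graph@bins
  e <- graph@edges
  n <- nbins(graph)
  chrom <- xmlEscape(b@chrom)
  if (dialect == "graphml") {
    head <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="chrom" for="node" attr.name="chrom" attr.type="string"/>',
      '  <key id="start" for="node" attr.name="start" attr.type="long"/>',
      '  <key id="end" for="node" attr.name="end" attr.type="long"/>',
      '  <key id="kind" for="edge" attr.name="kind" attr.type="string"/>',
      '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
      '  <graph id="G" edgedefault="undirected">')
    nodes <- sprintf(paste0(
      '    <node id="n%d"><data key="chrom">%s</data>',
      '<data key="start">%d</data><data key="end">%d</data></node>'),
      seq_len(n) - 1L, chrom, b@start, b@end)
    edgesx <- if (nrow(e)) sprintf(paste0(
      '    <edge source="n%d" target="n%d">',
      '<data key="kind">%s</data><data key="weight">%s</data></edge>'),
      e$u, e$v, e$kind, fmtNum(e$weight)) else character(0)
    writeLines(c(head, nodes, edgesx, "  </graph>", "</graphml>"), path)
  } else {
    head <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
      '  <graph mode="static" defaultedgetype="undirected">',
      '    <attributes class="node">',
      '      <attribute id="0" title="chrom" type="string"/>',
      '      <attribute id="1" title="start" type="long"/>',
      '      <attribute id="2" title="end" type="long"/>',
      '    </attributes>',
      '    <attributes class="edge">',
      '      <attribute id="3" title="kind" type="string"/>',
      '    </attributes>',
      '    <nodes>')
    lab <- xmlEscape(binLabels(b))
    nodes <- sprintf(paste0(
      '      <node id="%d" label="%s"><attvalues>',
      '<attvalue for="0" value="%s"/><attvalue for="1" value="%d"/>',
      '<attvalue for="2" value="%d"/></attvalues></node>'),
      seq_len(n) - 1L, lab, chrom, b@start, b@end)
    edgesx <- if (nrow(e)) sprintf(paste0(
      '      <edge id="%d" source="%d" target="%d" weight="%s">',
      '<attvalues><attvalue for="3" value="%s"/></attvalues></edge>'),
      seq_len(nrow(e)) - 1L, e$u, e$v, fmtNum(e$weight), e$kind)
      else character(0)
    writeLines(c(head, nodes, "    </nodes>", "    <edges>", edgesx,
                 "    </edges>", "  </graph>", "</gexf>"), path)
  }
  invisible(path)
}
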