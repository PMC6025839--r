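#' Stress-majorization layout of a Hi-C graph
#'
#' Computes a 2D embedding in the spirit of an edge-weighted spring
#' layout: every edge is given a target length equal to the inverse of its
#' (combined) weight, so a high interaction frequency pulls two bins close
#' together and the backbone edge has length \code{resolution}. Target
#' distances between all vertex pairs are the weighted shortest-path
#' distances under those edge lengths, and coordinates minimize the
#' normalized stress
#' \deqn{\sigma(X) = \sum_{u<v} (\|x_u - x_v\| - d_{uv})^2 / d_{uv}^2}
#' by SMACOF majorization from a seeded random start. Majorization
#' guarantees a non-increasing stress trace; iteration stops when the
#' relative stress decrease falls below \code{tol} or after \code{maxIter}
#' sweeps. Disconnected components (possible with an aggressive
#' \code{minFreq}) are laid out independently and packed left-to-right.
#' Runs are deterministic for a fixed seed.
#'
#' @param graph a [HiCGraph-class] with at least 2 vertices and 1 edge.
#' @param seed integer RNG seed for the random start.
#' @param maxIter maximum majorization sweeps per component.
#' @param tol relative stress-decrease threshold for convergence.
#' @param combine weight combination rule, see [effectiveWeights()].
#' @return a [LayoutResult-class] with \code{algorithm = "stress"}; the
#'   trace holds the stress after every sweep (summed over components,
#'   each padded with its converged value), starting from the initial
#'   configuration.
#' @export
stressLayout <- function(graph, seed = 1L, maxIter = 100L, tol = 1e-6,
                         combine = c("sum", "interaction_only")) {
  combine <- match.arg(combine)
  stopifnot(is(graph, "HiCGraph"))
  n <- nbins(graph)
  if (n < 2L) stopf("need at least 2 vertices to embed")
  if (nrow(graph@edges) == 0L) stopf("no edges to embed")
  if (maxIter < 1L) stopf("maxIter must be >= 1")

  ig <- asIgraph(graph, combine)
  len <- 1 / igraph::E(ig)$weight
  comp <- igraph::components(ig)
  D_full <- igraph::distances(ig, weights = len)

  parts <- vector("list", comp$no)
  traces <- vector("list", comp$no)
  withSeed(seed, {
    for (ci in seq_len(comp$no)) {
      idx <- which(comp$membership == ci)
      nc <- length(idx)
      if (nc == 1L) {
        parts[[ci]] <- matrix(0, 1L, 2L)
        traces[[ci]] <- 0
        next
      }
      D <- D_full[idx, idx, drop = FALSE]
      sm <- smacof2d(D, maxIter = maxIter, tol = tol)
      parts[[ci]] <- sm$X
      traces[[ci]] <- sm$trace
    }
  })

  pos <- packComponents(parts, comp$membership, n)
  tl <- max(vapply(traces, length, integer(1)))
  padded <- vapply(traces, function(tr)
    c(tr, rep.int(tr[length(tr)], tl - length(tr))), numeric(tl))
  trace <- if (tl == 1L) sum(padded) else rowSums(matrix(padded, nrow = tl))
  rownames(pos) <- binLabels(graph@bins)
  new("LayoutResult", positions = pos, trace = as.numeric(trace),
      seed = as.integer(seed), algorithm = "stress",
      params = list(maxIter = as.integer(maxIter), tol = tol,
                    combine = combine))
}

# SMACOF with weights 1/D^2 on a dense target-distance matrix (one
# connected component). Returns positions and the stress trace (initial
# configuration first). The Guttman transform never increases stress; a
# numerically zero or negative decrease terminates the loop so the
# recorded trace is non-increasing by construction.
smacof2d <- function(D, maxIter, tol) {
  nc <- nrow(D)
  W <- 1 / D^2
  diag(W) <- 0
  ut <- upper.tri(D)
  scale0 <- mean(D[ut])
  X <- matrix(stats::runif(nc * 2L, -1, 1), ncol = 2L) * scale0

  V <- -W
  diag(V) <- rowSums(W)
  Vi <- solve(V + 1)              # (V + 11')^{-1} acts as V^+ on B(X)X

  dd <- as.matrix(stats::dist(X))
  stress <- sum(W[ut] * (dd[ut] - D[ut])^2)
  trace <- stress
  for (it in seq_len(maxIter)) {
    ratio <- ifelse(dd > 0, D / dd, 0)
    B <- -W * ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- Vi %*% (B %*% X)
    dd <- as.matrix(stats::dist(X))
    s_new <- sum(W[ut] * (dd[ut] - D[ut])^2)
    if (s_new > stress) break     # fp guard; majorization forbids increase
    trace <- c(trace, s_new)
    done <- stress == 0 || (stress - s_new) / stress < tol
    stress <- s_new
    if (done) break
  }
  list(X = X, trace = trace)
}

# Center each component's coordinates and place the components
# left-to-right with a gap proportional to the largest component width.
packComponents <- function(parts, membership, n) {
  pos <- matrix(0, n, 2L)
  widths <- numeric(length(parts))
  for (ci in seq_along(parts)) {
    X <- parts[[ci]]
    X <- sweep(X, 2L, colMeans(X))
    parts[[ci]] <- X
    widths[ci] <- diff(range(X[, 1]))
  }
  gap <- 0.2 * max(widths, 1)
  offset <- 0
  for (ci in seq_along(parts)) {
    X <- parts[[ci]]
    X[, 1] <- X[, 1] + offset - min(X[, 1])
    pos[membership == ci, ] <- X
    offset <- offset + widths[ci] + gap
  }
  pos
}
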