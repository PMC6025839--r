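#' ForceAtlas2 layout of a Hi-C graph
#'
#' Force-directed embedding with the ForceAtlas2 force model: attraction
#' along every edge proportional to \code{w^delta * distance} (with
#' \code{delta} the edge-weight influence), degree-weighted repulsion
#' \code{kr * (deg_u + 1)(deg_v + 1) / distance} between every vertex
#' pair (exact O(N^2) evaluation — fast at the ~1258-bin scale of a yeast
#' genome), gravity of magnitude \code{g * (deg + 1)} toward the layout
#' centroid, and the adaptive swing-based speed rule: a vertex whose force
#' oscillates between steps (high swing) is slowed down, so no vertex
#' teleports. Runs exactly \code{iterations} steps and is deterministic
#' for a fixed seed.
#'
#' @param graph a [HiCGraph-class] with at least 1 vertex.
#' @param seed integer RNG seed for the random start.
#' @param iterations positive number of steps to run.
#' @param kr repulsion scaling constant.
#' @param gravity gravity strength toward the centroid.
#' @param edgeWeightInfluence exponent delta applied to edge weights in the
#'   attraction term (0 ignores weights, 1 uses them linearly).
#' @param jitterTolerance tolerance of the global speed heuristic; larger
#'   values allow faster, jerkier convergence.
#' @param combine weight combination rule, see [effectiveWeights()].
#' @return a [LayoutResult-class] with \code{algorithm = "forceatlas2"};
#'   the trace holds the mass-weighted global swing per step.
#' @export
forceAtlas2 <- function(graph, seed = 1L, iterations = 300L, kr = 2,
                        gravity = 1, edgeWeightInfluence = 1,
                        jitterTolerance = 1,
                        combine = c("sum", "interaction_only")) {
  combine <- match.arg(combine)
  stopifnot(is(graph, "HiCGraph"))
  if (iterations < 1L) stopf("iterations must be a positive integer")
  n <- nbins(graph)
  e <- graph@edges
  deg <- tabulate(c(e$u, e$v) + 1L, nbins = n)
  mass <- deg + 1

  wA <- effectiveWeights(graph, combine)^edgeWeightInfluence
  eu <- e$u + 1L
  ev <- e$v + 1L

  pos <- withSeed(seed, matrix(stats::runif(n * 2L, -1, 1), ncol = 2L) *
                          sqrt(n))
  pos <- sweep(pos, 2L, colMeans(pos))      # single vertex sits at origin
  massmat <- outer(mass, mass)
  diag(massmat) <- 0

  Fprev <- matrix(0, n, 2L)
  globalSpeed <- 1
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    # repulsion (exact pairwise)
    DX <- outer(pos[, 1], pos[, 1], "-")
    DY <- outer(pos[, 2], pos[, 2], "-")
    d2 <- DX * DX + DY * DY
    d2[d2 == 0] <- Inf
    Fx <- kr * rowSums(massmat * DX / d2)
    Fy <- kr * rowSums(massmat * DY / d2)

    # attraction along edges, proportional to distance
    if (nrow(e)) {
      ax <- wA * (pos[ev, 1] - pos[eu, 1])
      ay <- wA * (pos[ev, 2] - pos[eu, 2])
      sx <- rowsum(c(ax, -ax), c(eu, ev))
      sy <- rowsum(c(ay, -ay), c(eu, ev))
      who <- as.integer(rownames(sx))
      Fx[who] <- Fx[who] + sx[, 1]
      Fy[who] <- Fy[who] + sy[, 1]
    }

    # gravity: unit pull toward the current centroid, scaled by mass
    ctr <- colMeans(pos)
    gx <- ctr[1] - pos[, 1]
    gy <- ctr[2] - pos[, 2]
    gd <- sqrt(gx * gx + gy * gy)
    nzg <- gd > 0
    Fx[nzg] <- Fx[nzg] + gravity * mass[nzg] * gx[nzg] / gd[nzg]
    Fy[nzg] <- Fy[nzg] + gravity * mass[nzg] * gy[nzg] / gd[nzg]

    # adaptive speed from swing vs traction
    swing <- sqrt((Fx - Fprev[, 1])^2 + (Fy - Fprev[, 2])^2)
    traction <- sqrt((Fx + Fprev[, 1])^2 + (Fy + Fprev[, 2])^2) / 2
    gSwing <- sum(mass * swing)
    gTraction <- sum(mass * traction)
    if (gSwing > 0) {
      target <- jitterTolerance * gTraction / gSwing
      globalSpeed <- min(target, 1.5 * globalSpeed)
    }
    localSpeed <- 0.1 * globalSpeed / (1 + globalSpeed * sqrt(swing))
    fmag <- sqrt(Fx * Fx + Fy * Fy)
    dispMag <- fmag * localSpeed
    capfac <- ifelse(dispMag > 10, 10 / dispMag, 1)  # bounded step
    pos[, 1] <- pos[, 1] + Fx * localSpeed * capfac
    pos[, 2] <- pos[, 2] + Fy * localSpeed * capfac

    Fprev[, 1] <- Fx
    Fprev[, 2] <- Fy
    trace[it] <- gSwing
  }

  rownames(pos) <- binLabels(graph@bins)
  new("LayoutResult", positions = pos, trace = trace,
      seed = as.integer(seed), algorithm = "forceatlas2",
      params = list(iterations = as.integer(iterations), kr = kr,
                    gravity = gravity,
                    edgeWeightInfluence = edgeWeightInfluence,
                    jitterTolerance = jitterTolerance, combine = combine))
}
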