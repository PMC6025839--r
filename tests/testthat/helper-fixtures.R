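# Shared fixture builders: everything is generated in code at test time.

# 3 bins on one chromosome with a single 0.5-frequency contact between the
# outer bins; the running toy example.
toyBins <- function() generateBins(c(chrI = 30000), 10000)

toyMatrix <- function() {
  m <- matrix(0, 3, 3)
  m[1, 3] <- m[3, 1] <- 0.5
  ContactMatrix(m, toyBins())
}

toyGraph <- function(...) buildGraph(toyMatrix(), ...)

# Random multi-chromosome ContactMatrix for property tests. Controlled
# sparsity; symmetric non-negative with zero diagonal.
randomContactMatrix <- function(maxN = 50, maxC = 4, density = 0.3,
                                res = 1000, minC = 1) {
  C <- sample(minC:maxC, 1)
  sizes <- sample(seq_len(max(2, maxN %/% C)), C, replace = TRUE)
  while (sum(sizes) < 2) sizes <- sizes + 1L
  bins <- generateBins(stats::setNames(sizes * res, paste0("c", seq_len(C))),
                       res)
  n <- nbins(bins)
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  on <- sample(ut, ceiling(density * length(ut)))
  m[on] <- stats::runif(length(on), 0.01, 2)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ContactMatrix(m, bins)
}

# LayoutResult wrapper around raw coordinates (for metric tests).
asLayout <- function(pos) {
  new("LayoutResult", positions = as.matrix(pos), trace = numeric(0),
      seed = 0L, algorithm = "stress", params = list())
}

# Apply a rigid motion (rotation by theta + translation) to coordinates.
rigidMotion <- function(pos, theta, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pos %*% t(R), 2, -shift)
}

# Independent brute-force edge enumeration used as the oracle for
# buildGraph: a plain double loop over all pairs applying the published
# classification and weight rules directly.
bruteForceEdges <- function(cm, minFreq = 0, scale = 1) {
  bins <- binTable(cm)
  n <- nbins(bins)
  chrom <- binChrom(bins)
  v <- contactValues(cm)
  res <- resolution(bins)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      samechrom <- chrom[i] == chrom[j]
      adj <- samechrom && (j - i == 1)
      f <- v[i, j] * scale
      if (adj) {
        out[[length(out) + 1]] <- data.frame(
          u = i - 1L, v = j - 1L, kind = "linear", weight = 1 / res,
          measured_freq = if (f > minFreq) f else NA_real_)
      } else if (f > minFreq) {
        out[[length(out) + 1]] <- data.frame(
          u = i - 1L, v = j - 1L,
          kind = if (samechrom) "cis" else "trans",
          weight = f, measured_freq = NA_real_)
      }
    }
  }
  e <- do.call(rbind, out)
  e <- e[order(factor(e$kind, levels = c("linear", "cis", "trans")),
               e$u, e$v), , drop = FALSE]
  rownames(e) <- NULL
  e
}
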