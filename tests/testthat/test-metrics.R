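test_that("cisTransRatio sums weights and flags undefined cases", {
  b <- generateBins(c(A = 40000, B = 20000), 10000)
  m <- matrix(0, 6, 6)
  m[1, 3] <- m[3, 1] <- 0.5        # cis
  m[2, 4] <- m[4, 2] <- 1.5        # cis
  m[1, 5] <- m[5, 1] <- 1.0        # trans
  g <- buildGraph(ContactMatrix(m, b))
  expect_equal(cisTransRatio(g), 2.0)

  # no trans edges -> infinite flag; no interactions at all -> NaN flag
  m2 <- matrix(0, 6, 6); m2[1, 3] <- m2[3, 1] <- 0.5
  expect_true(is.infinite(cisTransRatio(buildGraph(ContactMatrix(m2, b)))))
  g0 <- buildGraph(ContactMatrix(matrix(0, 6, 6), b))
  expect_true(is.nan(cisTransRatio(g0)))
})

test_that("cisTransRatio is invariant to frequency scaling", {
  set.seed(8)
  for (rep in 1:10) {
    cm <- randomContactMatrix(maxN = 30, maxC = 3)
    r1 <- cisTransRatio(buildGraph(cm))
    for (k in c(0.2, 5)) {
      rk <- cisTransRatio(buildGraph(cm, scale = k))
      if (is.nan(r1)) expect_true(is.nan(rk))
      else expect_equal(rk, r1)
    }
  }
})

test_that("neighborhoodMixing hits its closed-form extremes", {
  # two distant compact clusters: no cross-chromosome neighbours
  b <- generateBins(c(A = 40000, B = 40000), 10000)
  clus <- rbind(cbind(stats::runif(4), stats::runif(4)),
                cbind(100 + stats::runif(4), stats::runif(4)))
  expect_equal(neighborhoodMixing(asLayout(clus), b, k = 3), 0)

  # alternating vertices on a line: every nearest neighbour is from the
  # other chromosome at k = 1
  bAB <- generateBins(c(A = 20000, B = 20000), 10000)
  pos <- cbind(c(0, 2, 1, 3), rep(0, 4))  # A at 0,2; B at 1,3
  expect_equal(neighborhoodMixing(asLayout(pos), bAB, k = 1), 1)
  expect_error(neighborhoodMixing(asLayout(pos), bAB, k = 4), "k must")
  expect_error(neighborhoodMixing(asLayout(pos), bAB, k = 0), "k must")
})

test_that("mixing breaks distance ties by lower bin index", {
  bAB <- generateBins(c(A = 20000, B = 20000), 10000)
  # vertex 0 at origin; vertices 1 (chrom A) and 2 (chrom B) equidistant;
  # the k=1 neighbour of vertex 0 must be bin 1 (lower index), and vertex
  # 2's tie between bins 0 and 3 resolves to bin 0
  pos <- cbind(c(0, 1, -1, -2), c(0, 0, 0, 0))
  val <- neighborhoodMixing(asLayout(pos), bAB, k = 1)
  # neighbours: v0->v1 (same), v1->v0 (same), v2->v0 (diff), v3->v2 (same)
  expect_equal(val, 0.25)
})

test_that("territorySeparation matches its closed form and permutation null", {
  # two tight clusters of spread s at centroid distance D -> D/s
  b <- generateBins(c(A = 40000, B = 40000), 10000)
  ring <- function(cx, r) cbind(cx + r * cos(1:4 * pi / 2),
                                r * sin(1:4 * pi / 2))
  pos <- rbind(ring(0, 1), ring(10, 1))     # spread = RMS radius = 1
  expect_equal(territorySeparation(asLayout(pos), b), 10)

  expect_error(
    territorySeparation(asLayout(pos),
                        generateBins(c(A = 80000), 10000)),
    "2 chromosomes")

  # shuffled labels on one cloud: statistic behaves like the permutation
  # null (oracle: 200 random relabellings)
  set.seed(99)
  cloud <- cbind(stats::rnorm(40), stats::rnorm(40))
  bins40 <- generateBins(c(A = 200000, B = 200000), 10000)
  lay <- asLayout(cloud)
  perm <- replicate(200, {
    sh <- cloud[sample(40), ]
    territorySeparation(asLayout(sh), bins40)
  })
  obs <- territorySeparation(asLayout(cloud[sample(40), ]), bins40)
  expect_gte(obs, min(perm))
  expect_lte(obs, max(perm))
})

test_that("layout metrics are invariant under rigid motions and scaling", {
  set.seed(21)
  cm <- randomContactMatrix(maxN = 30, maxC = 3)
  g <- buildGraph(cm)
  L <- stressLayout(g, seed = 1, maxIter = 40)
  bins <- binTable(g)
  k <- min(5L, nbins(bins) - 1L)
  mix0 <- neighborhoodMixing(L, bins, k = k)
  C <- length(unique(binChrom(bins)))
  ter0 <- if (C >= 2) territorySeparation(L, bins) else NA
  for (rep in 1:20) {
    theta <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(2, sd = 50)
    moved <- asLayout(rigidMotion(positions(L), theta, shift))
    expect_equal(neighborhoodMixing(moved, bins, k = k), mix0)
    if (C >= 2)
      expect_equal(territorySeparation(moved, bins), ter0)
    # uniform scaling preserves both (ranks and the spread ratio)
    sc <- asLayout(positions(L) * stats::runif(1, 0.1, 9))
    expect_equal(neighborhoodMixing(sc, bins, k = k), mix0)
    if (C >= 2)
      expect_equal(territorySeparation(sc, bins), ter0)
  }
})
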