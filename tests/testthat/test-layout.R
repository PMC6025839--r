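test_that("stress layout hits the 2-vertex closed form", {
  # single edge of weight w: the stress minimum puts the vertices at
  # distance exactly 1/w
  b <- generateBins(c(A = 20000), 10000)
  for (f in c(0.25, 0.8)) {
    m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- f
    g <- buildGraph(ContactMatrix(m, b))
    w <- 1e-4 + f                       # combine = "sum" on the backbone
    L <- stressLayout(g, seed = 4)
    expect_lt(abs(stats::dist(positions(L)) - 1 / w), 1e-6)
    L2 <- stressLayout(g, seed = 4, combine = "interaction_only")
    expect_lt(abs(stats::dist(positions(L2)) - 1 / f), 1e-6)
  }
})

test_that("stress trace is non-increasing and runs are deterministic", {
  set.seed(202)
  for (rep in 1:25) {
    cm <- randomContactMatrix(maxN = 25, density = stats::runif(1, 0.1, 0.5))
    g <- buildGraph(cm)
    L <- stressLayout(g, seed = rep, maxIter = 60)
    tr <- layoutTrace(L)
    expect_true(all(diff(tr) <= 0))
    expect_lte(tr[length(tr)], tr[1])
    expect_true(all(is.finite(positions(L))))
    # determinism contract: identical positions on rerun
    expect_identical(positions(stressLayout(g, seed = rep, maxIter = 60)),
                     positions(L))
  }
})

test_that("stronger interactions end up closer (3-vertex line)", {
  # one strong and one weak interaction: target distances 1/w are ordered,
  # so the embedded distances must be too
  b <- generateBins(c(A = 30000), 10000)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 2       # strong pair (0,1)
  m[2, 3] <- m[3, 2] <- 0.2     # weak pair (1,2)
  g <- buildGraph(ContactMatrix(m, b))
  L <- stressLayout(g, seed = 9)
  d <- as.matrix(stats::dist(positions(L)))
  expect_lt(d[1, 2], d[2, 3])
})

test_that("stress layout packs disconnected components and flags no edges", {
  # aggressive threshold on a 2-chromosome map with no trans contacts:
  # two backbone components laid out separately
  b <- generateBins(c(A = 30000, B = 30000), 10000)
  m <- matrix(0, 6, 6)
  m[1, 3] <- m[3, 1] <- 1
  m[4, 6] <- m[6, 4] <- 1
  g <- buildGraph(ContactMatrix(m, b))
  L <- stressLayout(g, seed = 2)
  pos <- positions(L)
  expect_true(all(is.finite(pos)))
  # components do not overlap horizontally
  expect_lt(max(pos[1:3, 1]), min(pos[4:6, 1]))

  g0 <- new("HiCGraph", bins = generateBins(c(A = 20000), 10000),
            edges = edges(g)[0, ], resolution = 10000L)
  expect_error(stressLayout(g0), "no edges")
  expect_error(stressLayout(toyGraph(), maxIter = 0), "maxIter")
})

test_that("forceatlas2 is deterministic, bounded and respects iterations", {
  set.seed(77)
  cm <- randomContactMatrix(maxN = 20, density = 0.4)
  g <- buildGraph(cm)
  L1 <- forceAtlas2(g, seed = 5, iterations = 80)
  L2 <- forceAtlas2(g, seed = 5, iterations = 80)
  expect_identical(positions(L1), positions(L2))
  expect_length(layoutTrace(L1), 80L)
  expect_true(all(is.finite(positions(L1))))
  # different seeds explore different starts
  L3 <- forceAtlas2(g, seed = 6, iterations = 80)
  expect_false(identical(positions(L1), positions(L3)))
  expect_error(forceAtlas2(g, iterations = 0), "positive")
})

test_that("forceatlas2 separates disconnected cliques; single vertex at origin", {
  # two 5-bin chromosomes, all within-chromosome pairs interacting, no
  # trans: repulsion must push the cliques apart further than their
  # internal spread
  b <- generateBins(c(A = 50000, B = 50000), 10000)
  m <- matrix(0, 10, 10)
  code <- rep(1:2, each = 5)
  for (i in 1:9) for (j in (i + 1):10)
    if (code[i] == code[j]) m[i, j] <- m[j, i] <- 1
  g <- buildGraph(ContactMatrix(m, b))
  L <- forceAtlas2(g, seed = 11, iterations = 500)
  pos <- positions(L)
  cA <- colMeans(pos[1:5, ]); cB <- colMeans(pos[6:10, ])
  inter <- sqrt(sum((cA - cB)^2))
  intra <- mean(c(stats::dist(pos[1:5, ]), stats::dist(pos[6:10, ])))
  expect_gt(inter, intra)

  # single vertex: gravity fixed point at the origin
  b1 <- generateBins(c(solo = 8000), 10000)
  g1 <- buildGraph(ContactMatrix(matrix(0, 1, 1), b1))
  Ls <- forceAtlas2(g1, seed = 1, iterations = 10)
  expect_equal(unname(positions(Ls)), matrix(0, 1, 2))
})

test_that("positions round-trip through the TSV writer", {
  cm <- randomContactMatrix(maxN = 15)
  g <- buildGraph(cm)
  L <- stressLayout(g, seed = 3, maxIter = 30)
  path <- withr::local_tempfile()
  writePositions(L, binTable(g), path)
  back <- readPositions(path)
  expect_equal(unname(back$layout@positions), unname(positions(L)))
  expect_equal(binLabels(back$bins), binLabels(binTable(g)))
  # byte-identical rewrite
  path2 <- withr::local_tempfile()
  writePositions(L, binTable(g), path2)
  expect_identical(readLines(path), readLines(path2))
})
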