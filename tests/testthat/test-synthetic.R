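test_that("noiseless simulation matches the closed-form expectations", {
  sp <- syntheticSpec(chromSizes = c(A = 50000, B = 30000),
                      resolution = 10000, alpha = 1.2, c0 = 0.8,
                      transBase = 0.04, territoryStrength = 0,
                      condensation = 0, noiseSd = 0)
  v <- contactValues(simulateContactMap(sp)$matrix)
  expect_equal(v[1, 3], 0.8 * 2^(-1.2))          # separation 2
  expect_equal(v[1, 2], 0.8)                     # separation 1
  expect_equal(v[1, 6], 0.04)                    # trans baseline
  expect_true(all(diag(v) == 0))
  expect_true(isSymmetric(v))

  # condensation boosts cis and damps trans by the stated factors
  spk <- syntheticSpec(chromSizes = c(A = 50000, B = 30000),
                       resolution = 10000, alpha = 1.2, c0 = 0.8,
                       transBase = 0.04, territoryStrength = 0,
                       condensation = 1.5, noiseSd = 0)
  vk <- contactValues(simulateContactMap(spk)$matrix)
  expect_equal(vk[1, 3], 2.5 * v[1, 3])
  expect_equal(vk[1, 6], v[1, 6] / 2.5)

  # perfect territories: all trans entries exactly 0
  spt <- syntheticSpec(chromSizes = c(A = 50000, B = 30000),
                       resolution = 10000, territoryStrength = 1,
                       noiseSd = 0.4, seed = 3)
  vt <- contactValues(simulateContactMap(spt)$matrix)
  code <- rep(1:2, c(5, 3))
  expect_true(all(vt[outer(code, code, "!=")] == 0))
})

test_that("simulation is deterministic in the seed and validates ranges", {
  sp <- syntheticSpec(chromSizes = c(A = 2e5), resolution = 1e4,
                      noiseSd = 0.3, seed = 12)
  m1 <- contactValues(simulateContactMap(sp)$matrix)
  m2 <- contactValues(simulateContactMap(sp)$matrix)
  expect_identical(m1, m2)
  sp2 <- syntheticSpec(chromSizes = c(A = 2e5), resolution = 1e4,
                       noiseSd = 0.3, seed = 13)
  expect_false(identical(m1, contactValues(simulateContactMap(sp2)$matrix)))

  expect_error(syntheticSpec(alpha = 0), "alpha")
  expect_error(syntheticSpec(territoryStrength = 1.2), "territoryStrength")
  expect_error(syntheticSpec(condensation = -1), "condensation")
  expect_error(syntheticSpec(noiseSd = -0.1), "noiseSd")
  expect_error(syntheticSpec(c0 = 0), "c0")
})

test_that("simulated maps satisfy ContactMatrix invariants and feed the pipeline", {
  sim <- simulateContactMap(syntheticSpec(chromSizes = c(A = 3e5, B = 2e5),
                                          resolution = 1e4, seed = 4))
  expect_true(validObject(sim$matrix))
  g <- buildGraph(sim$matrix)
  L <- stressLayout(g, seed = 1, maxIter = 30)
  expect_true(all(is.finite(positions(L))))
  expect_gt(cisTransRatio(g), 0)
  expect_gte(neighborhoodMixing(L, sim$bins, k = 5), 0)
  expect_gt(territorySeparation(L, sim$bins), 0)
})

test_that("fitDecayExponent recovers alpha exactly in the noiseless limit", {
  for (a in c(0.5, 1.0, 1.5)) {
    sp <- syntheticSpec(chromSizes = c(A = 3e6), resolution = 1e4,
                        alpha = a, noiseSd = 0)
    expect_lt(abs(fitDecayExponent(simulateContactMap(sp)$matrix) - a),
              1e-6)
  }
  # too few separations
  spb <- syntheticSpec(chromSizes = c(A = 30000), resolution = 1e4,
                       noiseSd = 0)
  expect_error(fitDecayExponent(simulateContactMap(spb)$matrix),
               "3 distinct")
})

test_that("decay recovery under noise stays within the Monte-Carlo band", {
  # 300-bin genome, lognormal noise sd 0.3, 5 seeds; +-0.1 band verified
  # generously by a 50-seed pilot (sd of estimates ~0.002)
  est <- vapply(1:5, function(s) {
    sp <- syntheticSpec(chromSizes = c(A = 3e6), resolution = 1e4,
                        alpha = 1, noiseSd = 0.3, seed = s)
    fitDecayExponent(simulateContactMap(sp)$matrix)
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("condensation raises the cis/trans ratio (closed-form direction)", {
  # noiseless: ratio is exactly proportional to (1+k)^2 via the expected
  # frequencies, so strict monotonicity must hold
  r <- vapply(c(0, 0.5, 1, 2), function(k) {
    sp <- syntheticSpec(chromSizes = c(A = 2e5, B = 1.5e5),
                        resolution = 1e4, condensation = k, noiseSd = 0)
    cisTransRatio(buildGraph(simulateContactMap(sp)$matrix))
  }, numeric(1))
  expect_true(all(diff(r) > 0))
  expect_equal(r[3] / r[1], 4, tolerance = 1e-12)   # (1+1)^2 / (1+0)^2
})

test_that("presets move the stated parameters in the stated directions", {
  wt <- syntheticPreset("wildtype")
  rad <- syntheticPreset("rad21")
  mph <- syntheticPreset("mphase")
  expect_lt(rad@territoryStrength, wt@territoryStrength)
  expect_lt(rad@c0, wt@c0)
  expect_gt(mph@condensation, wt@condensation)
  expect_equal(nbins(binTable(wt)), 1258L)
})
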