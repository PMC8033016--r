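planarSite <- function(nr = 4, nc = 4) {
  arr <- ElectrodeArray(nr, nc)
  sig <- matrix(0, nr * nc, 100)
  sig[, 50] <- 1  # content irrelevant for map plumbing
  SiteRecording(arr, "RA", sig, reference = numeric(100))
}

test_that("activation maps respect grid shape and channel quality", {
  site <- planarSite()
  lat <- matrix(seq(0, 30, length.out = 16), 4, 4)
  m <- buildActivationMap(site, lat, beat = 1L)
  expect_s4_class(m, "ActivationMap")
  expect_equal(sum(!is.na(latMatrix(m))), 16L)
  expect_equal(sum(excludedMask(m)), 0L)

  site2 <- planarSite()
  site2@channelQuality[3] <- FALSE   # row 1, col 3 (row-major)
  m2 <- buildActivationMap(site2, lat, beat = 1L)
  expect_equal(sum(!is.na(latMatrix(m2))), 15L)
  expect_true(is.na(latMatrix(m2)[1, 3]))

  site3 <- planarSite()
  site3@channelQuality[] <- FALSE
  expect_warning(m3 <- buildActivationMap(site3, lat), "empty")
  expect_equal(sum(!is.na(latMatrix(m3))), 0L)

  expect_error(buildActivationMap(site, matrix(0, 3, 3)), "3 x 3")
})

test_that("simultaneous-activation plateaus are excluded, gradients are not", {
  site <- planarSite(5, 5)
  ## gradient with an embedded 3x3 plateau of identical LATs
  lat <- outer(1:5, 1:5, function(r, cc) 2 * r + 40 * cc)
  lat[2:4, 2:4] <- 77
  m <- excludeSimultaneousAreas(buildActivationMap(site, lat), AnalysisParams())
  expect_equal(sum(excludedMask(m)), 9L)
  expect_true(all(excludedMask(m)[2:4, 2:4]))

  ## strict planar gradient: nothing excluded at tolerance 0
  lat2 <- outer(1:5, 1:5, function(r, cc) 2 * r + 10 * cc)
  m2 <- excludeSimultaneousAreas(buildActivationMap(site, lat2),
                                 AnalysisParams())
  expect_equal(sum(excludedMask(m2)), 0L)

  ## two identical electrodes only: component of 2 < 4, kept
  lat3 <- lat2
  lat3[1, 2] <- lat3[1, 1]
  m3 <- excludeSimultaneousAreas(buildActivationMap(site, lat3),
                                 AnalysisParams())
  expect_equal(sum(excludedMask(m3)), 0L)
})

test_that("the 12 ms conduction-block threshold is inclusive", {
  site <- planarSite(1, 2)
  p <- AnalysisParams()
  m <- detectConductionBlock(
    excludeSimultaneousAreas(
      buildActivationMap(site, matrix(c(10, 22), 1, 2)), p), p)
  expect_equal(nrow(cbEdges(m)), 1L)      # delta exactly 12: block
  expect_equal(cbPercentage(m), 100)
  m2 <- detectConductionBlock(
    excludeSimultaneousAreas(
      buildActivationMap(site, matrix(c(10, 21.9), 1, 2)), p), p)
  expect_equal(nrow(cbEdges(m2)), 0L)
  expect_equal(cbPercentage(m2), 0)
})

test_that("block detection equals the brute-force pair scan on random grids", {
  p <- AnalysisParams()
  site <- planarSite(6, 6)
  for (seed in 1:200) {
    set.seed(seed)
    lat <- matrix(runif(36, 0, 40), 6, 6)
    lat[sample(36, 3)] <- NA           # some electrodes without potential
    m <- buildActivationMap(site, lat)
    m <- excludeSimultaneousAreas(m, p)
    m <- suppressWarnings(detectConductionBlock(m, p))
    want <- cbOracle(latMatrix(m), excludedMask(m), p@cbThresholdMs)
    got <- as.matrix(cbEdges(m)[, 1:4])
    expect_setequal(edgeKey(got), edgeKey(want$edges))
    expect_equal(m@evaluablePairs, want$nEval)
  }
})

test_that("block edges are invariant to a constant LAT shift", {
  p <- AnalysisParams()
  site <- planarSite(6, 6)
  set.seed(11)
  lat <- matrix(runif(36, 0, 40), 6, 6)
  m1 <- detectConductionBlock(buildActivationMap(site, lat), p)
  m2 <- detectConductionBlock(buildActivationMap(site, lat + 123.4), p)
  expect_equal(cbEdges(m1), cbEdges(m2))
})

test_that("raising the block threshold never adds edges", {
  site <- planarSite(6, 6)
  set.seed(5)
  lat <- matrix(runif(36, 0, 60), 6, 6)
  counts <- vapply(c(8, 12, 16, 20, 30), function(thr) {
    m <- detectConductionBlock(buildActivationMap(site, lat),
                               AnalysisParams(cbThresholdMs = thr))
    nrow(cbEdges(m))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planar propagation shows no block; a delayed line blocks exactly there", {
  ## planar wavefront at CV >= 0.2 mm/ms on 2 mm spacing: max neighbour
  ## delta-LAT 10 ms, no block
  cfg <- SimulationConfig(cvMmPerMs = 0.2, directionDeg = 0, noiseSigmaMv = 0,
                          nBeats = 1, durationS = 1, firstBeatMs = 200)
  truth <- generateLatField(cfg)
  lat <- latMatrix(truth)
  m <- detectConductionBlock(
    buildActivationMap(planarSite(8, 8), lat), AnalysisParams())
  expect_equal(nrow(cbEdges(m)), 0L)
  expect_equal(cbPercentage(m), 0)

  ## insert a full block line with delay >= 12: block exactly on the
  ## straddling pairs
  cfg2 <- SimulationConfig(cvMmPerMs = 1, directionDeg = 0, noiseSigmaMv = 0,
                           nBeats = 1, durationS = 1, firstBeatMs = 200,
                           blockLines = blockLine(7.5, -10, 7.5, 24, 20))
  truth2 <- generateLatField(cfg2)
  m2 <- detectConductionBlock(
    buildActivationMap(planarSite(8, 8), latMatrix(truth2)),
    AnalysisParams())
  e <- cbEdges(m2)
  expect_equal(nrow(e), 8L)                       # one edge per row
  expect_true(all(e$col1 == 4 & e$col2 == 5))     # all straddling the line
  expect_true(all(e$dlat_ms >= 12))
})
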