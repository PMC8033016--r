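test_that("a plane wave along the array gives exact neighbour LAT steps", {
  cfg <- SimulationConfig(cvMmPerMs = 1.0, directionDeg = 0, noiseSigmaMv = 0,
                          nBeats = 1, durationS = 1, firstBeatMs = 200)
  lat <- latMatrix(generateLatField(cfg))
  ## spacing 2.0 mm at 1.0 mm/ms: 2.0 ms per column, constant per column
  expect_equal(unname(diff(lat[1, ])), rep(2, 7))
  expect_true(all(apply(lat, 2, function(col) all(col == col[1]))))
})

test_that("a focal source gives a symmetric distance-proportional field", {
  cfg <- SimulationConfig(sourceType = "focal", focalOriginMm = c(7, 7),
                          cvMmPerMs = 1.0, noiseSigmaMv = 0,
                          nBeats = 1, durationS = 1, firstBeatMs = 200)
  lat <- latMatrix(generateLatField(cfg))
  expect_equal(lat, lat[8:1, ])       # mirror symmetry
  expect_equal(lat, t(lat))           # diagonal symmetry
  expect_true(which.min(lat) %in% c(28L, 29L, 36L, 37L))  # centre first
})

test_that("a delayed block line separates the two sides by >= its delay", {
  cfg <- SimulationConfig(cvMmPerMs = 1.0, directionDeg = 0, noiseSigmaMv = 0,
                          nBeats = 1, durationS = 1, firstBeatMs = 200,
                          blockLines = blockLine(7.5, -10, 7.5, 24, 20))
  truth <- generateLatField(cfg)
  lat <- latMatrix(truth)
  expect_true(all(lat[, 5] - lat[, 4] >= 20))
  ## expected CB pairs are exactly the straddling rook pairs
  expect_equal(nrow(truth@cbExpected), 8L)
  expect_true(all(truth@cbExpected$col1 == 4 & truth@cbExpected$col2 == 5))
})

test_that("simulation is bitwise reproducible from its seed", {
  s1 <- simulateSite(smallTemplate(seed = 77L))$site
  s2 <- simulateSite(smallTemplate(seed = 77L))$site
  expect_identical(signals(s1), signals(s2))
  s3 <- simulateSite(smallTemplate(seed = 78L))$site
  expect_false(identical(signals(s1), signals(s3)))

  g1 <- generatePatient(blockDensity = 1, seed = 5L,
                        template = smallTemplate())
  g2 <- generatePatient(blockDensity = 1, seed = 5L,
                        template = smallTemplate())
  for (k in seq_along(sites(g1$dataset)))
    expect_identical(signals(sites(g1$dataset)[[k]]),
                     signals(sites(g2$dataset)[[k]]))
})

test_that("interior electrodes yield one clean detected deflection", {
  cfg <- SimulationConfig(noiseSigmaMv = 0.05, seed = 13L)  # SNR ~ 100
  s <- simulateSite(cfg)
  res <- analyzeSite(s$site)
  pot <- res$potentials
  interior <- pot[pot$row %in% 3:6 & pot$col %in% 3:6, ]
  expect_true(mean(interior$n_deflections == 1) >= 0.99)
})

test_that("electrodes at a block line record long double potentials", {
  cfg <- SimulationConfig(blockLines = blockLine(7.5, -10, 7.5, 24, 20),
                          noiseSigmaMv = 0.05, seed = 17L)
  s <- simulateSite(cfg)
  res <- analyzeSite(s$site)
  pot <- res$potentials
  strad <- pot[pot$col %in% c(4, 5), ]
  expect_true(mean(strad$n_deflections >= 2) > 0.9)
  expect_true(mean(strad$type == "LDP") > 0.5)
  ## the deflection gap at straddling electrodes tracks the crossing delay
  ldp <- strad[strad$type == "LDP", ]
  expect_equal(median(ldp$fd_ms), 20, tolerance = 0.25)
})

test_that("the focal origin shows a solely-S morphology (R/S near +1)", {
  cfg <- SimulationConfig(sourceType = "focal", focalOriginMm = c(7, 7),
                          noiseSigmaMv = 0, seed = 19L)
  s <- simulateSite(cfg)
  res <- analyzeSite(s$site)
  pot <- res$potentials
  centre <- pot[pot$row == 4 & pot$col == 4 & pot$beat == 1, ]
  expect_equal(centre$type, "SP")
  expect_lt(centre$r_mv, 0.25 * centre$s_mv)
  expect_gt(centre$rs_ratio, 0.75)
})

test_that("block density drives conduction block and fractionation", {
  for (seed in c(101L, 202L, 303L)) {
    lo <- generatePatient(blockDensity = 0, seed = seed,
                          template = smallTemplate())
    hi <- generatePatient(blockDensity = 2.5, seed = seed,
                          template = smallTemplate())
    fpLo <- buildFingerprint(lo$dataset)
    fpHi <- buildFingerprint(hi$dataset)
    expect_gt(overallFingerprint(fpHi)@pctCb,
              overallFingerprint(fpLo)@pctCb)
    expect_gt(ldpFpBurden(fpHi), ldpFpBurden(fpLo))
  }
})

test_that("annotated LATs recover the simulated truth", {
  ## noise free: within +-1 ms everywhere
  cfg <- smallTemplate(noiseSigmaMv = 0, cvMmPerMs = 1.0)
  s <- simulateSite(cfg)
  res <- analyzeSite(s$site)
  pot <- res$potentials
  tru <- latMatrix(s$truth)
  bt <- s$truth@beatTimesMs
  err <- pot$lat_ms - (bt[pot$beat] + tru[cbind(pot$row, pot$col)])
  expect_true(mean(abs(err) <= 1) >= 0.99)
})
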