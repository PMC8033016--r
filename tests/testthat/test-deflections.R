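makeReference <- function(fidMs, n = 5000) {
  ref <- numeric(n)
  ref[fidMs + 1L] <- 1
  ref
}

test_that("beat segmentation finds fiducials and flags premature beats", {
  p <- AnalysisParams()
  b <- segmentBeats(makeReference(c(500, 1500, 2500, 3500, 4500)), 1000, p)
  expect_equal(nrow(b), 5L)
  expect_equal(b$reference_time_ms, c(500, 1500, 2500, 3500, 4500))
  expect_true(all(b$accepted))
  expect_true(all(b$end_ms > b$start_ms))
  ## non-overlap
  expect_true(all(diff(as.vector(rbind(b$start_ms, b$end_ms))) >= 0))

  ## premature beat: extra fiducial at 1800 (cycle 300 vs median 1000);
  ## by the preceding-cycle rule the 2500 beat (cycle 700 < 750) is
  ## rejected as well
  b2 <- segmentBeats(makeReference(c(500, 1500, 1800, 2500, 3500, 4500)),
                     1000, p)
  expect_equal(nrow(b2), 6L)
  expect_false(b2$accepted[b2$reference_time_ms == 1800])
  expect_false(b2$accepted[b2$reference_time_ms == 2500])
  expect_true(all(b2$accepted[b2$reference_time_ms %in% c(500, 1500, 3500, 4500)]))
})

test_that("flat reference yields no beats, with a warning", {
  expect_warning(b <- segmentBeats(numeric(1000), 1000), "no beats")
  expect_equal(nrow(b), 0L)
})

test_that("noise estimate recovers a known sigma and ignores beats", {
  windows <- data.frame(start_ms = c(400, 1400), end_ms = c(700, 1700),
                        reference_time_ms = c(500, 1500),
                        accepted = TRUE)
  ## Monte-Carlo: pure Gaussian noise of sd 0.05 mV
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    x <- rnorm(2000, sd = 0.05)
    sigmaMv(estimateNoise(x, windows[0, ], 1000)) / 0.05 - 1
  }, numeric(1))
  expect_true(all(abs(errs) < 0.15))

  ## large beats confined to the windows leave sigma unaffected
  set.seed(99)
  x <- rnorm(2000, sd = 0.05)
  xb <- x
  xb[401:700] <- xb[401:700] + biphasicTemplate(0:299, 150, 3, 6)
  xb[1401:1700] <- xb[1401:1700] + biphasicTemplate(0:299, 150, 3, 6)
  s0 <- sigmaMv(estimateNoise(x, windows, 1000))
  s1 <- sigmaMv(estimateNoise(xb, windows, 1000))
  expect_equal(s1, s0, tolerance = 0.15)

  expect_error(estimateNoise(numeric(1000), windows), "degenerate")
  expect_warning(
    estimateNoise(rnorm(100), data.frame(start_ms = 0, end_ms = 200,
                                         reference_time_ms = 100,
                                         accepted = TRUE), 1000),
    "quiescent")
})

test_that("a clean biphasic wave yields one deflection at the analytic optimum", {
  tt <- 0:299
  x <- biphasicTemplate(tt, 100, 1, 2)
  d <- detectDeflections(x, list(start_ms = 0, end_ms = 299),
                         NoiseEstimate(0.05), AnalysisParams())
  expect_equal(nrow(d), 1L)
  ## analytic steepest-descent time and extrema of the continuous template
  f <- function(t) biphasicTemplate(t, 100, 1, 2)
  g <- function(t) (f(t + 1e-4) - f(t - 1e-4)) / 2e-4
  tStar <- optimize(g, c(80, 120))$minimum
  rStar <- optimize(f, c(80, 105), maximum = TRUE)$objective
  sStar <- -optimize(f, c(95, 130))$objective
  expect_lt(abs(d$t_ms - tStar), 1 + 1e-9)        # within one sample
  expect_equal(d$r_mv, rStar, tolerance = 0.05)
  expect_equal(d$s_mv, sStar, tolerance = 0.05)
  expect_lt(d$slope_mv_per_ms, 0)
})

test_that("two templates 20 ms apart yield two deflections 20 ms apart", {
  tt <- 0:299
  x <- biphasicTemplate(tt, 100, 1, 2) + biphasicTemplate(tt, 120, 1, 2)
  d <- detectDeflections(x, list(start_ms = 0, end_ms = 299),
                         NoiseEstimate(0.05), AnalysisParams())
  expect_equal(nrow(d), 2L)
  expect_equal(diff(d$t_ms), 20, tolerance = 1)
})

test_that("a deflection below twice the noise level is rejected", {
  tt <- 0:299
  sigma <- 0.05
  x <- biphasicTemplate(tt, 100, 1, 2) * (1.5 * sigma / 3)  # vpp ~ 1.5 sigma
  d <- detectDeflections(x, list(start_ms = 0, end_ms = 299),
                         NoiseEstimate(sigma), AnalysisParams())
  expect_equal(nrow(d), 0L)
})

test_that("deflection lists are ordered and separated", {
  set.seed(7)
  p <- AnalysisParams()
  for (i in 1:25) {
    tt <- 0:299
    nDef <- sample(1:4, 1)
    centers <- sort(sample(seq(60, 240, by = 4), nDef))
    x <- rowSums(vapply(centers, function(cc)
      biphasicTemplate(tt, cc, runif(1, 0.5, 2), runif(1, 0.5, 3)),
      numeric(length(tt)))) + rnorm(length(tt), sd = 0.03)
    d <- detectDeflections(x, list(start_ms = 0, end_ms = 299),
                           NoiseEstimate(0.03), p)
    if (nrow(d) >= 2L) {
      expect_true(all(diff(d$t_ms) > 0))
      expect_true(all(diff(d$t_ms) >= p@minDeflectionSeparationMs))
    }
  }
})

test_that("deflection counts are stable under mild added noise", {
  ## per-electrode deflection counts must be unchanged for >= 95% of
  ## electrodes when Gaussian noise with sigma <= vpp/20 is added
  cfg <- smallTemplate(noiseSigmaMv = 0)
  s <- simulateSite(cfg)
  sig <- signals(s$site)
  p <- AnalysisParams()
  w <- list(start_ms = 300, end_ms = 600)
  vpp <- median(apply(sig[, 301:601], 1, function(x) max(x) - min(x)))
  noiseSigma <- vpp / 20
  base <- vapply(seq_len(nrow(sig)), function(e)
    nrow(detectDeflections(sig[e, ], w, NoiseEstimate(noiseSigma), p)),
    integer(1))
  fracSame <- vapply(1:50, function(seed) {
    set.seed(1000 + seed)
    cnt <- vapply(seq_len(nrow(sig)), function(e) {
      x <- sig[e, ] + rnorm(ncol(sig), sd = noiseSigma)
      nrow(detectDeflections(x, w, NoiseEstimate(noiseSigma), p))
    }, integer(1))
    mean(cnt == base)
  }, numeric(1))
  expect_true(mean(fracSame) >= 0.95)
})

test_that("LAT is the time of the steepest negative slope", {
  d <- data.frame(t_ms = c(30, 42), slope_mv_per_ms = c(-2, -5),
                  r_mv = c(1, 1), s_mv = c(1, 1), vpp_mv = c(2, 2))
  expect_equal(annotateLat(d), 42)
  expect_equal(annotateLat(d[1, ]), 30)
  expect_true(is.na(annotateLat(d[0, ])))
})
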