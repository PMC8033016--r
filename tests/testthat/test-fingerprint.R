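## constructed potential table with known composition
makePotentials <- function(nSp = 80, nSdp = 10, nLdp = 6, nFp = 4) {
  n <- nSp + nSdp + nLdp + nFp
  types <- rep(c("SP", "SDP", "LDP", "FP"), c(nSp, nSdp, nLdp, nFp))
  data.frame(
    patient_id = "p", region = "RA", site_id = "s1",
    row = rep(1:10, length.out = n), col = rep(1:10, each = 10)[1:n],
    beat = 1L, type = types, lat_ms = 500 + seq_len(n),
    r_mv = 1, s_mv = 2, rs_ratio = ifelse(types == "SP", 0.5, NA),
    vpp_mv = seq(0.5, 6, length.out = n),
    low_voltage = seq(0.5, 6, length.out = n) < 1,
    fd_ms = ifelse(types == "SP", 0, 18), n_deflections = 1L,
    deflection_times_ms = "500")
}

test_that("region summaries count types and conserve percentages", {
  pot <- makePotentials()
  fp <- summarizeRegion(pot, list(), "RA")
  expect_equal(fp@pctSp, 80)
  expect_equal(fp@pctSdp, 10)
  expect_equal(fp@pctLdp, 6)
  expect_equal(fp@pctFp, 4)
  expect_equal(fp@pctSp + fp@pctSdp + fp@pctLdp + fp@pctFp, 100,
               tolerance = 1e-12)
  expect_equal(fp@nPotentials, 100L)
  expect_equal(fp@medianVoltageMv, median(pot$vpp_mv))
  expect_equal(fp@pctLowVoltage, 100 * mean(pot$low_voltage))
  expect_equal(fp@medianRsRatio, 0.5)
  expect_equal(fp@medianFdMs, 18)
  ## histogram counts sum to the population sizes
  expect_equal(sum(fp@histograms$voltage$counts), 100)
  expect_equal(sum(fp@histograms$rs$counts), 80)       # SPs only
  expect_equal(sum(fp@histograms$fd$counts), 20)       # multi-deflection
  ## empty region
  e <- summarizeRegion(pot[0, ], list(), "LA")
  expect_equal(e@nPotentials, 0L)
})

test_that("fingerprints carry one entry per mapped region plus a pooled entry", {
  a <- simulateSite(smallTemplate(seed = 41L), region = "RA",
                    siteId = "RA_s1")$site
  b <- simulateSite(smallTemplate(seed = 42L), region = "BB",
                    siteId = "BB_s1")$site
  ds <- PatientDataset("pt10", list(a, b))
  fp <- buildFingerprint(ds)
  expect_s4_class(fp, "PatientFingerprint")
  expect_equal(names(regionFingerprints(fp)), c("RA", "BB"))
  ov <- overallFingerprint(fp)
  expect_equal(ov@nPotentials,
               sum(vapply(regionFingerprints(fp),
                          function(r) r@nPotentials, integer(1))))
  expect_equal(ov@pctSp + ov@pctSdp + ov@pctLdp + ov@pctFp, 100,
               tolerance = 1e-9)
  expect_equal(ldpFpBurden(fp), ov@pctLdp + ov@pctFp)

  ## running the pipeline twice produces a byte-identical document
  t1 <- tempfile(); t2 <- tempfile()
  writeFingerprint(buildFingerprint(ds), t1)
  writeFingerprint(buildFingerprint(ds), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("signal maps report per-electrode type fractions", {
  pot <- data.frame(
    patient_id = "p", region = "RA", site_id = "s", row = 1L, col = 1L,
    beat = 1:5, type = c("SP", "SP", "SP", "LDP", "LDP"),
    lat_ms = 1, r_mv = 1, s_mv = 1, rs_ratio = NA, vpp_mv = 2,
    low_voltage = FALSE, fd_ms = 0, n_deflections = 1L,
    deflection_times_ms = "1")
  sm <- signalMap(pot)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$f_sp, 0.6)
  expect_equal(sm$f_ldp, 0.4)
  expect_equal(sm$f_sdp + sm$f_fp, 0)
  expect_equal(sm$f_sp + sm$f_sdp + sm$f_ldp + sm$f_fp, 1)
  ## an electrode with no classified beat is absent
  expect_equal(nrow(signalMap(pot[0, ])), 0L)
})

test_that("fractionation concentrates on electrodes straddling a block line", {
  cfg <- SimulationConfig(blockLines = blockLine(7.5, -10, 7.5, 24, 20),
                          noiseSigmaMv = 0.05, seed = 23L)
  s <- simulateSite(cfg)
  res <- analyzeSite(s$site)
  sm <- signalMap(res$potentials)
  strad <- sm$col %in% c(4, 5)
  ratio <- mean(sm$f_ldp[strad] + sm$f_fp[strad]) /
    max(mean(sm$f_ldp[!strad] + sm$f_fp[!strad]), 1e-9)
  expect_gt(ratio, 2)
})

test_that("patients rank by fractionation burden with stable ties", {
  fps <- list(patientFpStub("pA", pctCb = 2, pctLdp = 5),
              patientFpStub("pB", pctCb = 1, pctLdp = 2),
              patientFpStub("pC", pctCb = 4, pctLdp = 9))
  ranked <- rankPatients(fps)
  expect_equal(vapply(ranked, patientId, character(1)),
               c("pB", "pA", "pC"))
  ## equal burdens: lexicographic patient id
  tied <- list(patientFpStub("z2", 1, 3), patientFpStub("a1", 1, 3))
  expect_equal(vapply(rankPatients(tied), patientId, character(1)),
               c("a1", "z2"))
})

test_that("higher block density yields strictly higher burden, pairwise", {
  ## 8 sites per patient so a high-density patient cannot plausibly draw
  ## an (almost) line-free substrate
  wins <- 0L
  nPairs <- 20L
  for (k in seq_len(nPairs)) {
    seed <- 400L + k
    lo <- buildFingerprint(generatePatient(0.2, nSitesPerRegion = 2,
                                           seed = seed,
                                           template = smallTemplate())$dataset)
    hi <- buildFingerprint(generatePatient(2.5, nSitesPerRegion = 2,
                                           seed = seed,
                                           template = smallTemplate())$dataset)
    wins <- wins + (ldpFpBurden(hi) > ldpFpBurden(lo))
  }
  expect_equal(wins, nPairs)
})
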