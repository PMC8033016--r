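## shared fixtures and independent oracles used across the test files

## small, fast simulation template for property tests
smallTemplate <- function(...) {
  SimulationConfig(gridRows = 6, gridCols = 6, nBeats = 3,
                   cycleLengthMs = 1000, firstBeatMs = 400,
                   durationS = 3.2, ...)
}

## analytic biphasic electrogram template: R lobe then S lobe
biphasicTemplate <- function(t, t0, R, S, sig = 3, del = 4) {
  R * exp(-(t - t0 + del)^2 / (2 * sig^2)) -
    S * exp(-(t - t0 - del)^2 / (2 * sig^2))
}

## direct restatement of the classification rules (oracle)
classifyOracle <- function(times, boundary = 15, fpMin = 3) {
  n <- length(times)
  if (n == 0L) return(NA_character_)
  times <- sort(times)
  if (n >= fpMin) return("FP")
  if (n == 1L) return("SP")
  if (times[2L] - times[1L] < boundary) "SDP" else "LDP"
}

## direct restatement of the piecewise R/S formula (oracle)
rsOracle <- function(r, s) {
  if (r == 0) return(1)
  if (s == 0) return(-1)
  q <- r / s
  if (q <= 1) 1 - q else 1 / q - 1
}

## brute-force conduction-block scan over all rook-adjacent pairs (oracle)
cbOracle <- function(lat, excluded, thr) {
  nr <- nrow(lat); nc <- ncol(lat)
  edges <- NULL
  nEval <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    for (d in list(c(0L, 1L), c(1L, 0L))) {
      r2 <- r + d[1L]; c2 <- cc + d[2L]
      if (r2 > nr || c2 > nc) next
      if (is.na(lat[r, cc]) || is.na(lat[r2, c2])) next
      if (excluded[r, cc] || excluded[r2, c2]) next
      nEval <- nEval + 1L
      if (abs(lat[r, cc] - lat[r2, c2]) >= thr)
        edges <- rbind(edges, c(r, cc, r2, c2))
    }
  }
  list(edges = edges, nEval = nEval)
}

## brute-force Spearman rho from the rank formula (no ties)
spearmanOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

## canonical CB-edge key for set comparison
edgeKey <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(character())
  apply(m, 1L, function(e) paste(e, collapse = "-"))
}

## minimal hand-built RegionFingerprint for stats tests
regionFpStub <- function(region, pctCb, pctLdp, medianVoltage = 5,
                         pctLow = 5, rs = 0.5, pctSdp = 5, pctFp = 1,
                         fd = 10) {
  pctSp <- 100 - pctSdp - pctLdp - pctFp
  new("RegionFingerprint", region = region, nPotentials = 100L,
      medianVoltageMv = medianVoltage, pctLowVoltage = pctLow,
      medianRsRatio = rs, pctSp = pctSp, pctSdp = pctSdp,
      pctLdp = pctLdp, pctFp = pctFp, medianFdMs = fd, pctCb = pctCb,
      histograms = list())
}

patientFpStub <- function(id, pctCb, pctLdp, ...) {
  ov <- regionFpStub("ALL", pctCb, pctLdp, ...)
  regs <- list(RA = regionFpStub("RA", pctCb, pctLdp, ...))
  new("PatientFingerprint", patientId = id, regions = regs,
      overall = ov, paramsEcho = paramsAsList(AnalysisParams()),
      ldpFpBurden = ov@pctLdp + ov@pctFp, pipelineVersion = "test")
}
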