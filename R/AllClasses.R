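#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- arrays --

#' ElectrodeArray: geometry of a regular mapping array
#'
#' Describes the rectangular multielectrode array used for epicardial
#' mapping: number of rows and columns, interelectrode spacing (mm) and
#' row-major electrode labels. The clinically used arrays have 128 or 192
#' electrodes at 2.0 mm spacing, but any positive grid is accepted.
#'
#' @slot nRows,nCols integer grid dimensions
#' @slot spacingMm interelectrode distance in millimetres
#' @slot electrodeIds character vector of labels, row-major order
#'
#' @aliases nRows,ElectrodeArray-method nCols,ElectrodeArray-method
#'   spacingMm,ElectrodeArray-method electrodeIds,ElectrodeArray-method
#' @export
setClass("ElectrodeArray",
  representation(nRows = "integer", nCols = "integer",
                 spacingMm = "numeric", electrodeIds = "character"))

setValidity("ElectrodeArray", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single positive integer")
  if (length(object@spacingMm) != 1L || is.na(object@spacingMm) ||
      object@spacingMm <= 0)
    msg <- c(msg, "spacingMm must be a single positive number")
  if (length(msg) == 0L &&
      length(object@electrodeIds) != object@nRows * object@nCols)
    msg <- c(msg, "electrodeIds must have length nRows * nCols")
  if (length(msg)) msg else TRUE
})

#' Construct an ElectrodeArray
#'
#' @param nRows,nCols grid dimensions
#' @param spacingMm interelectrode distance (mm), default 2.0
#' @param electrodeIds optional labels (row-major); generated as
#'   \code{E001, E002, ...} when missing
#' @return an [ElectrodeArray-class] object
#' @examples
#' ElectrodeArray(8, 8)
#' @export
ElectrodeArray <- function(nRows, nCols, spacingMm = 2.0, electrodeIds = NULL) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (is.null(electrodeIds))
    electrodeIds <- sprintf("E%03d", seq_len(nRows * nCols))
  new("ElectrodeArray", nRows = nRows, nCols = nCols,
      spacingMm = as.numeric(spacingMm),
      electrodeIds = as.character(electrodeIds))
}

#' @export
setMethod("nRows", "ElectrodeArray", function(x) x@nRows)
#' @export
setMethod("nCols", "ElectrodeArray", function(x) x@nCols)
#' @export
setMethod("spacingMm", "ElectrodeArray", function(x) x@spacingMm)
#' @export
setMethod("electrodeIds", "ElectrodeArray", function(x) x@electrodeIds)

setMethod("show", "ElectrodeArray", function(object) {
  cat(sprintf("ElectrodeArray: %d x %d electrodes (n = %d), %.1f mm spacing\n",
              object@nRows, object@nCols, object@nRows * object@nCols,
              object@spacingMm))
})

## ------------------------------------------------------------- recording --

#' SiteRecording: one mapping position
#'
#' A multichannel unipolar electrogram recording at a single mapping site:
#' a signed voltage matrix (electrodes x samples, mV), the array geometry,
#' the atrial region label, sampling metadata, a single-channel reference
#' trace used for beat segmentation, and a per-electrode quality flag.
#' Channels flagged \code{FALSE} in \code{channelQuality} are excluded from
#' every downstream statistic; their sample values are ignored entirely.
#'
#' @slot array [ElectrodeArray-class] geometry
#' @slot region one of \code{RA}, \code{BB}, \code{PVA}, \code{LA}
#' @slot signals numeric matrix, electrodes (row-major) x samples, mV
#' @slot fsHz sampling rate, Hz (1000 in the clinical acquisition chain)
#' @slot reference numeric reference trace, same length as the recording
#' @slot channelQuality logical per-electrode include flag
#' @slot siteId character label
#' @export
setClass("SiteRecording",
  representation(array = "ElectrodeArray", region = "character",
                 signals = "matrix", fsHz = "numeric", reference = "numeric",
                 channelQuality = "logical", siteId = "character"))

setValidity("SiteRecording", function(object) {
  msg <- character()
  nel <- object@array@nRows * object@array@nCols
  if (!(object@region %in% REGIONS))
    msg <- c(msg, sprintf("region '%s' invalid; allowed regions: %s",
                          object@region, paste(REGIONS, collapse = ", ")))
  if (nrow(object@signals) != nel)
    msg <- c(msg, "signals must have one row per electrode")
  if (length(object@channelQuality) != nel)
    msg <- c(msg, "channelQuality must have one flag per electrode")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a single positive number")
  if (length(object@reference) != ncol(object@signals))
    msg <- c(msg, "reference must have one value per sample")
  ## only included channels must be finite
  if (length(msg) == 0L) {
    good <- which(object@channelQuality)
    bad <- good[!vapply(good, function(i) all(is.finite(object@signals[i, ])),
                        logical(1))]
    if (length(bad))
      msg <- c(msg, sprintf("non-finite samples on included channel(s): %s",
                            paste(head(bad, 5L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SiteRecording
#'
#' @param array an [ElectrodeArray-class]
#' @param region atrial region label (\code{RA}, \code{BB}, \code{PVA},
#'   \code{LA})
#' @param signals electrodes x samples voltage matrix (mV, row-major
#'   electrode order)
#' @param fsHz sampling rate (Hz), default 1000
#' @param reference reference trace for beat timing (defaults to the mean of
#'   the included channels)
#' @param channelQuality logical include flag per electrode (default all
#'   \code{TRUE})
#' @param siteId site label
#' @return a [SiteRecording-class]
#' @export
SiteRecording <- function(array, region, signals, fsHz = 1000,
                          reference = NULL, channelQuality = NULL,
                          siteId = "site1") {
  if (is.null(channelQuality))
    channelQuality <- rep(TRUE, nrow(signals))
  if (is.null(reference))
    reference <- colMeans(signals[channelQuality, , drop = FALSE])
  new("SiteRecording", array = array, region = as.character(region),
      signals = signals, fsHz = as.numeric(fsHz),
      reference = as.numeric(reference),
      channelQuality = as.logical(channelQuality),
      siteId = as.character(siteId))
}

#' @export
setMethod("region", "SiteRecording", function(x) x@region)
#' @export
setMethod("signals", "SiteRecording", function(x) x@signals)
#' @export
setMethod("referenceTrace", "SiteRecording", function(x) x@reference)
#' @export
setMethod("channelQuality", "SiteRecording", function(x) x@channelQuality)
#' @export
setMethod("samplingRate", "SiteRecording", function(x) x@fsHz)
#' @export
setMethod("durationS", "SiteRecording", function(x) ncol(x@signals) / x@fsHz)
#' @export
setMethod("siteId", "SiteRecording", function(x) x@siteId)
#' @export
setMethod("electrodeGrid", "SiteRecording", function(x) x@array)

setMethod("show", "SiteRecording", function(object) {
  cat(sprintf(
    "SiteRecording '%s' [%s]: %d electrodes x %d samples @ %g Hz (%.2f s), %d excluded channel(s)\n",
    object@siteId, object@region, nrow(object@signals), ncol(object@signals),
    object@fsHz, durationS(object), sum(!object@channelQuality)))
})

## --------------------------------------------------------------- dataset --

#' PatientDataset: all mapping sites of one patient
#'
#' @slot patientId character label
#' @slot sites list of [SiteRecording-class] objects
#' @slot metadata free-form key/value list (age, sex, ... optional)
#' @export
setClass("PatientDataset",
  representation(patientId = "character", sites = "list",
                 metadata = "list"))

setValidity("PatientDataset", function(object) {
  ok <- vapply(object@sites, is, logical(1), class2 = "SiteRecording")
  if (all(ok)) TRUE else "all sites must be SiteRecording objects"
})

#' Construct a PatientDataset
#'
#' @param patientId patient label
#' @param sites list of [SiteRecording-class] objects
#' @param metadata optional key/value list
#' @return a [PatientDataset-class]
#' @export
PatientDataset <- function(patientId, sites = list(), metadata = list()) {
  new("PatientDataset", patientId = as.character(patientId),
      sites = sites, metadata = metadata)
}

#' @export
setMethod("patientId", "PatientDataset", function(x) x@patientId)
#' @export
setMethod("sites", "PatientDataset", function(x) x@sites)
#' @export
setMethod("metadata", "PatientDataset", function(x) x@metadata)

setMethod("show", "PatientDataset", function(object) {
  regs <- vapply(object@sites, region, character(1))
  cat(sprintf("PatientDataset '%s': %d site(s)", object@patientId,
              length(object@sites)))
  if (length(regs))
    cat(" [", paste(sprintf("%s: %d", names(table(regs)), table(regs)),
                    collapse = ", "), "]", sep = "")
  cat("\n")
})

## ---------------------------------------------------------------- params --

#' AnalysisParams: thresholds and constants of the fingerprint pipeline
#'
#' Houses every tunable constant of the analysis. Defaults follow the
#' clinical convention: double potentials split into short/long at a 15 ms
#' deflection interval, fractionated potentials have >= 3 deflections,
#' conduction block is an LAT difference >= 12 ms between adjacent
#' electrodes, low voltage is a peak-to-peak amplitude < 1.0 mV, and a
#' deflection must exceed twice the noise level to be retained. The full
#' parameter set is echoed into every output document for provenance.
#'
#' @slot sdpLdpBoundaryMs SDP/LDP interval boundary, ms (interval <
#'   boundary is short, >= boundary is long); default 15
#' @slot fpMinDeflections minimum deflection count of a fractionated
#'   potential; default 3
#' @slot cbThresholdMs conduction-block LAT difference threshold, ms
#'   (inclusive); default 12
#' @slot lowVoltageMv low-voltage cut-off, mV (strict \code{<}); default 1.0
#' @slot snrFactor deflection amplitude gate in noise-sigma units; default 2
#' @slot minDeflectionSeparationMs merge distance for candidate downstrokes,
#'   ms; default 2
#' @slot simultaneityToleranceMs neighbour LAT tolerance defining
#'   simultaneous-activation areas, ms; default 0
#' @slot simultaneityMinArea minimum connected-component size (electrodes)
#'   of an excluded simultaneous area; default 4
#' @slot beatPreMs,beatPostMs beat window around the reference fiducial, ms;
#'   defaults 100 / 200
#' @slot prematureBeatFraction a beat whose preceding cycle length is below
#'   this fraction of the median cycle is rejected; default 0.75
#' @slot bandpassLowHz,bandpassHighHz acquisition bandwidth, Hz (0.5-400)
#' @slot applyBandpass logical; re-filter traces to the acquisition band
#'   before detection (off by default: the clinical chain already filters)
#' @slot slopeGateFactor candidate downstroke gate in units of the noise sd
#'   propagated through the derivative filter; default 3
#' @slot noiseFloorMv lower bound on the usable noise sigma, mV; default 0.01
#' @export
setClass("AnalysisParams",
  representation(sdpLdpBoundaryMs = "numeric", fpMinDeflections = "numeric",
                 cbThresholdMs = "numeric", lowVoltageMv = "numeric",
                 snrFactor = "numeric", minDeflectionSeparationMs = "numeric",
                 simultaneityToleranceMs = "numeric",
                 simultaneityMinArea = "numeric",
                 beatPreMs = "numeric", beatPostMs = "numeric",
                 prematureBeatFraction = "numeric",
                 bandpassLowHz = "numeric", bandpassHighHz = "numeric",
                 applyBandpass = "logical",
                 slopeGateFactor = "numeric", noiseFloorMv = "numeric"))

setValidity("AnalysisParams", function(object) {
  msg <- character()
  pos <- c("sdpLdpBoundaryMs", "fpMinDeflections", "cbThresholdMs",
           "lowVoltageMv", "snrFactor", "minDeflectionSeparationMs",
           "beatPreMs", "beatPostMs", "prematureBeatFraction",
           "bandpassLowHz", "bandpassHighHz", "slopeGateFactor",
           "noiseFloorMv")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(object@simultaneityToleranceMs) != 1L ||
      object@simultaneityToleranceMs < 0)
    msg <- c(msg, "simultaneityToleranceMs must be >= 0")
  if (length(msg) == 0L &&
      object@sdpLdpBoundaryMs >= object@beatPreMs + object@beatPostMs)
    msg <- c(msg, "sdpLdpBoundaryMs must be below the beat window length")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisParams object
#'
#' All arguments default to the values documented in
#' [AnalysisParams-class]; pass only what you want to override.
#'
#' @param sdpLdpBoundaryMs,fpMinDeflections,cbThresholdMs,lowVoltageMv,snrFactor,minDeflectionSeparationMs,simultaneityToleranceMs,simultaneityMinArea,beatPreMs,beatPostMs,prematureBeatFraction,bandpassLowHz,bandpassHighHz,applyBandpass,slopeGateFactor,noiseFloorMv
#'   see [AnalysisParams-class]
#' @return an [AnalysisParams-class]
#' @examples
#' AnalysisParams(cbThresholdMs = 14)
#' @export
AnalysisParams <- function(sdpLdpBoundaryMs = 15, fpMinDeflections = 3,
                           cbThresholdMs = 12, lowVoltageMv = 1.0,
                           snrFactor = 2.0, minDeflectionSeparationMs = 2,
                           simultaneityToleranceMs = 0,
                           simultaneityMinArea = 4,
                           beatPreMs = 100, beatPostMs = 200,
                           prematureBeatFraction = 0.75,
                           bandpassLowHz = 0.5, bandpassHighHz = 400,
                           applyBandpass = FALSE,
                           slopeGateFactor = 4.5, noiseFloorMv = 0.01) {
  new("AnalysisParams",
      sdpLdpBoundaryMs = sdpLdpBoundaryMs,
      fpMinDeflections = fpMinDeflections,
      cbThresholdMs = cbThresholdMs, lowVoltageMv = lowVoltageMv,
      snrFactor = snrFactor,
      minDeflectionSeparationMs = minDeflectionSeparationMs,
      simultaneityToleranceMs = simultaneityToleranceMs,
      simultaneityMinArea = simultaneityMinArea,
      beatPreMs = beatPreMs, beatPostMs = beatPostMs,
      prematureBeatFraction = prematureBeatFraction,
      bandpassLowHz = bandpassLowHz, bandpassHighHz = bandpassHighHz,
      applyBandpass = applyBandpass,
      slopeGateFactor = slopeGateFactor, noiseFloorMv = noiseFloorMv)
}

#' Serialize analysis parameters to a plain list
#'
#' Used to echo the full effective parameter set into every output document.
#'
#' @param params an [AnalysisParams-class]
#' @return a named list of scalars
#' @export
paramsAsList <- function(params) {
  stopifnot(is(params, "AnalysisParams"))
  sl <- slotNames(params)
  out <- lapply(sl, function(s) slot(params, s))
  names(out) <- sl
  out
}

setMethod("show", "AnalysisParams", function(object) {
  cat("AnalysisParams:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-26s %s\n", s, format(slot(object, s))))
})

## ----------------------------------------------------------------- noise --

#' NoiseEstimate: per-channel noise level
#'
#' @slot sigmaMv robust noise sigma, mV
#' @slot method label of the estimation method
#' @export
setClass("NoiseEstimate",
  representation(sigmaMv = "numeric", method = "character"))

setValidity("NoiseEstimate", function(object) {
  if (length(object@sigmaMv) != 1L || is.na(object@sigmaMv) ||
      object@sigmaMv <= 0) "sigmaMv must be a single positive number"
  else TRUE
})

#' Construct a NoiseEstimate
#' @param sigmaMv noise sigma (mV)
#' @param method method label
#' @return a [NoiseEstimate-class]
#' @export
NoiseEstimate <- function(sigmaMv, method = "mad") {
  new("NoiseEstimate", sigmaMv = as.numeric(sigmaMv),
      method = as.character(method))
}

#' @export
setMethod("sigmaMv", "NoiseEstimate", function(x) x@sigmaMv)

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: sigma = %.4g mV (%s)\n",
              object@sigmaMv, object@method))
})

## ------------------------------------------------------------ activation --

#' ActivationMap: per-beat LAT grid with exclusion mask and block edges
#'
#' Local activation times of one beat on the electrode grid, the mask of
#' electrodes excluded as simultaneous-activation (far-field) areas, and the
#' set of adjacent electrode pairs whose LAT difference reaches the
#' conduction-block threshold.
#'
#' @slot latMs numeric nRows x nCols matrix of LATs (ms, absolute recording
#'   time); \code{NA} where no potential was annotated
#' @slot excluded logical matrix, \code{TRUE} for excluded electrodes
#' @slot cbEdges data.frame with columns \code{row1,col1,row2,col2,dlat_ms}
#' @slot beat beat index
#' @slot evaluablePairs number of adjacent pairs entering the CB denominator
#' @slot cbPercentage 100 * blocked / evaluable pairs (\code{NA} when no
#'   pair is evaluable)
#' @export
setClass("ActivationMap",
  representation(latMs = "matrix", excluded = "matrix", cbEdges = "data.frame",
                 beat = "integer", evaluablePairs = "integer",
                 cbPercentage = "numeric"))

setValidity("ActivationMap", function(object) {
  msg <- character()
  if (!identical(dim(object@latMs), dim(object@excluded)))
    msg <- c(msg, "latMs and excluded must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("latMatrix", "ActivationMap", function(x) x@latMs)
#' @export
setMethod("excludedMask", "ActivationMap", function(x) x@excluded)
#' @export
setMethod("cbEdges", "ActivationMap", function(x) x@cbEdges)
#' @export
setMethod("cbPercentage", "ActivationMap", function(x) x@cbPercentage)

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf(
    "ActivationMap (beat %d): %d/%d LATs, %d excluded, %d CB edge(s)%s\n",
    object@beat, sum(!is.na(object@latMs)), length(object@latMs),
    sum(object@excluded), nrow(object@cbEdges),
    if (is.na(object@cbPercentage)) ""
    else sprintf(" (CB %.2f%%)", object@cbPercentage)))
})

## ----------------------------------------------------------- fingerprint --

#' RegionFingerprint: quantified EGM features of one atrial region
#'
#' The per-region summary of the signal fingerprint: median unipolar
#' voltage, proportion of low-voltage potentials, median R/S ratio of single
#' potentials, type proportions, median fractionation duration of
#' multi-deflection potentials, conduction-block percentage, and the
#' relative frequency distributions (voltage, R/S, FD) stacked by type.
#'
#' @slot region region label, or \code{"ALL"} for the pooled entry
#' @slot nPotentials number of classified electrode-beats
#' @slot medianVoltageMv,pctLowVoltage,medianRsRatio,pctSp,pctSdp,pctLdp,pctFp,medianFdMs,pctCb
#'   scalar features (\code{NA} when the underlying population is empty)
#' @slot histograms list with elements \code{voltage}, \code{rs}, \code{fd};
#'   each has \code{breaks} and a \code{counts} matrix stacked by type
#' @export
setClass("RegionFingerprint",
  representation(region = "character", nPotentials = "integer",
                 medianVoltageMv = "numeric", pctLowVoltage = "numeric",
                 medianRsRatio = "numeric", pctSp = "numeric",
                 pctSdp = "numeric", pctLdp = "numeric", pctFp = "numeric",
                 medianFdMs = "numeric", pctCb = "numeric",
                 histograms = "list"))

setValidity("RegionFingerprint", function(object) {
  msg <- character()
  if (object@nPotentials > 0L) {
    s <- object@pctSp + object@pctSdp + object@pctLdp + object@pctFp
    if (!isTRUE(abs(s - 100) < 1e-9))
      msg <- c(msg, "type percentages must sum to 100")
    pcts <- c(object@pctSp, object@pctSdp, object@pctLdp, object@pctFp,
              object@pctLowVoltage)
    if (any(pcts < 0 | pcts > 100, na.rm = TRUE))
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (!is.na(object@medianRsRatio) &&
        (object@medianRsRatio < -1 || object@medianRsRatio > 1))
      msg <- c(msg, "medianRsRatio must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegionFingerprint", function(object) {
  cat(sprintf("RegionFingerprint [%s]: n = %d\n", object@region,
              object@nPotentials))
  fmt2 <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", x)
  if (object@nPotentials > 0L)
    cat(sprintf(
      "  voltage %s mV | low-voltage %s%% | R/S %s | SP/SDP/LDP/FP %.1f/%.1f/%.1f/%.1f%% | FD %s ms | CB %s%%\n",
      fmt2(object@medianVoltageMv), fmt2(object@pctLowVoltage),
      fmt2(object@medianRsRatio), object@pctSp, object@pctSdp,
      object@pctLdp, object@pctFp, fmt2(object@medianFdMs),
      fmt2(object@pctCb)))
})

#' PatientFingerprint: the per-patient signal fingerprint document
#'
#' @slot patientId patient label
#' @slot regions named list of [RegionFingerprint-class], one per mapped
#'   region
#' @slot overall pooled [RegionFingerprint-class] over all regions (every
#'   potential weighted equally)
#' @slot paramsEcho list echo of the [AnalysisParams-class] used
#' @slot ldpFpBurden pooled pctLdp + pctFp (the fractionation burden used to
#'   rank patients)
#' @slot pipelineVersion package version string
#' @export
setClass("PatientFingerprint",
  representation(patientId = "character", regions = "list",
                 overall = "RegionFingerprint", paramsEcho = "list",
                 ldpFpBurden = "numeric", pipelineVersion = "character"))

setValidity("PatientFingerprint", function(object) {
  msg <- character()
  if (!all(vapply(object@regions, is, logical(1), class2 = "RegionFingerprint")))
    msg <- c(msg, "regions must be RegionFingerprint objects")
  else {
    nSum <- sum(vapply(object@regions, function(r) r@nPotentials, integer(1)))
    if (nSum != object@overall@nPotentials)
      msg <- c(msg, "overall count must equal the sum of regional counts")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("patientId", "PatientFingerprint", function(x) x@patientId)
#' @export
setMethod("regionFingerprints", "PatientFingerprint", function(x) x@regions)
#' @export
setMethod("overallFingerprint", "PatientFingerprint", function(x) x@overall)
#' @export
setMethod("ldpFpBurden", "PatientFingerprint", function(x) x@ldpFpBurden)

setMethod("show", "PatientFingerprint", function(object) {
  cat(sprintf("PatientFingerprint '%s': %d region(s), n = %d, LDP+FP burden %.2f%%\n",
              object@patientId, length(object@regions),
              object@overall@nPotentials, object@ldpFpBurden))
  for (r in object@regions) show(r)
})

## ------------------------------------------------------------- simulator --

#' SimulationConfig: parameters of the wavefront/EGM forward simulator
#'
#' Defines one simulated mapping site: the electrode grid, the activation
#' source (plane wave or focal), conduction velocity, block lines (linear
#' barriers with a crossing delay), beat train, the source waveform and the
#' distance weighting of the forward model, and additive noise. All
#' randomness flows from \code{seed}.
#'
#' @slot gridRows,gridCols electrode grid size
#' @slot spacingMm interelectrode distance (mm)
#' @slot sourceType \code{"plane"} or \code{"focal"}
#' @slot directionDeg plane-wave direction (degrees; 0 = along the column
#'   axis)
#' @slot focalOriginMm (x, y) of the focal origin in grid coordinates (mm)
#' @slot cvMmPerMs conduction velocity (mm/ms)
#' @slot blockLines data.frame \code{x0,y0,x1,y1,delay_ms} of block segments
#' @slot nBeats,cycleLengthMs,firstBeatMs beat train (defaults: 5 beats,
#'   1000 ms cycle, first fiducial at 500 ms)
#' @slot durationS recording length (s), default 5
#' @slot kernelWidthMs width of the per-node source pulse (ms)
#' @slot amplitudeMv source pulse amplitude scale (mV)
#' @slot decayExponent distance-weight exponent
#' @slot truncationRadiusMm forward-model truncation radius (mm)
#' @slot farFieldGain gain applied to sources beyond \code{farFieldRadiusMm}
#' @slot farFieldRadiusMm near/far boundary (mm), default 4
#' @slot tissueMarginMm tissue lattice margin beyond the array (mm)
#' @slot refineFactor tissue lattice refinement relative to the electrode
#'   spacing
#' @slot noiseSigmaMv additive Gaussian noise sigma (mV)
#' @slot seed RNG seed
#' @export
setClass("SimulationConfig",
  representation(gridRows = "integer", gridCols = "integer",
                 spacingMm = "numeric", sourceType = "character",
                 directionDeg = "numeric", focalOriginMm = "numeric",
                 cvMmPerMs = "numeric", blockLines = "data.frame",
                 nBeats = "integer", cycleLengthMs = "numeric",
                 firstBeatMs = "numeric", durationS = "numeric",
                 kernelWidthMs = "numeric", amplitudeMv = "numeric",
                 decayExponent = "numeric", truncationRadiusMm = "numeric",
                 farFieldGain = "numeric", farFieldRadiusMm = "numeric",
                 tissueMarginMm = "numeric", refineFactor = "integer",
                 noiseSigmaMv = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@cvMmPerMs <= 0) msg <- c(msg, "cvMmPerMs must be > 0")
  if (nrow(object@blockLines) &&
      any(object@blockLines$delay_ms < 0))
    msg <- c(msg, "block-line delays must be >= 0")
  if (!(object@sourceType %in% c("plane", "focal")))
    msg <- c(msg, "sourceType must be 'plane' or 'focal'")
  lastBeat <- object@firstBeatMs + (object@nBeats - 1L) * object@cycleLengthMs
  if (lastBeat >= object@durationS * 1000)
    msg <- c(msg, "beat train must fit within the recording duration")
  if (object@noiseSigmaMv < 0) msg <- c(msg, "noiseSigmaMv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the clinical acquisition: an 8 x 8 unipolar array at
#' 2.0 mm spacing, 5 s of sinus rhythm at a 1000 ms cycle length, a plane
#' wave at 0.9 mm/ms, and 0.05 mV additive noise. See
#' [SimulationConfig-class] for all slots.
#'
#' @param gridRows,gridCols,spacingMm,sourceType,directionDeg,focalOriginMm,cvMmPerMs,blockLines,nBeats,cycleLengthMs,firstBeatMs,durationS,kernelWidthMs,amplitudeMv,decayExponent,truncationRadiusMm,farFieldGain,farFieldRadiusMm,tissueMarginMm,refineFactor,noiseSigmaMv,seed
#'   see [SimulationConfig-class]
#' @return a [SimulationConfig-class]
#' @examples
#' cfg <- SimulationConfig(gridRows = 4, gridCols = 4, nBeats = 2,
#'                         durationS = 2)
#' @export
SimulationConfig <- function(gridRows = 8, gridCols = 8, spacingMm = 2.0,
                             sourceType = "plane", directionDeg = 30,
                             focalOriginMm = c(0, 0), cvMmPerMs = 0.9,
                             blockLines = emptyBlockLines(),
                             nBeats = 5, cycleLengthMs = 1000,
                             firstBeatMs = 500, durationS = 5,
                             kernelWidthMs = 8, amplitudeMv = 1.3,
                             decayExponent = 3, truncationRadiusMm = 6,
                             farFieldGain = 1, farFieldRadiusMm = 4,
                             tissueMarginMm = 4, refineFactor = 2,
                             noiseSigmaMv = 0.05, seed = 1L) {
  new("SimulationConfig", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), spacingMm = spacingMm,
      sourceType = sourceType, directionDeg = directionDeg,
      focalOriginMm = focalOriginMm, cvMmPerMs = cvMmPerMs,
      blockLines = blockLines, nBeats = as.integer(nBeats),
      cycleLengthMs = cycleLengthMs, firstBeatMs = firstBeatMs,
      durationS = durationS, kernelWidthMs = kernelWidthMs,
      amplitudeMv = amplitudeMv, decayExponent = decayExponent,
      truncationRadiusMm = truncationRadiusMm, farFieldGain = farFieldGain,
      farFieldRadiusMm = farFieldRadiusMm, tissueMarginMm = tissueMarginMm,
      refineFactor = as.integer(refineFactor),
      noiseSigmaMv = noiseSigmaMv, seed = as.integer(seed))
}

#' Empty block-line table
#'
#' @return zero-row data.frame with columns \code{x0,y0,x1,y1,delay_ms}
#' @export
emptyBlockLines <- function() {
  data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
             y1 = numeric(), delay_ms = numeric())
}

#' Build a block-line table
#'
#' Block lines are linear conduction barriers in grid coordinates
#' (x along columns, y along rows, mm); a lattice edge crossing the segment
#' incurs \code{delay_ms} of extra travel time.
#'
#' @param x0,y0,x1,y1 segment endpoints (mm)
#' @param delay_ms crossing delay (ms)
#' @return data.frame usable as \code{blockLines} in [SimulationConfig()]
#' @export
blockLine <- function(x0, y0, x1, y1, delay_ms) {
  data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1, delay_ms = delay_ms)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %dx%d grid @ %.1f mm, %s source, CV %.2f mm/ms, %d block line(s), %d beat(s), noise %.3f mV, seed %d\n",
    object@gridRows, object@gridCols, object@spacingMm, object@sourceType,
    object@cvMmPerMs, nrow(object@blockLines), object@nBeats,
    object@noiseSigmaMv, object@seed))
})

## ---------------------------------------------------------- ground truth --

#' GroundTruth: simulator ground truth for one site
#'
#' @slot latMs electrode LAT matrix (rows x cols) of the first beat, in ms
#'   relative to the beat fiducial
#' @slot beatTimesMs fiducial times of all beats (ms, absolute)
#' @slot tissueLat list with the tissue lattice (\code{xs}, \code{ys},
#'   \code{lat} matrix, relative ms)
#' @slot blockLines block-line table used
#' @slot cbExpected data.frame of electrode pairs expected to show
#'   conduction block (geodesic LAT difference >= 12 ms across a line)
#' @slot expectedType character matrix of geometry-derived expected types
#'   (\code{"SP"} away from lines, \code{"LDP"} near a delaying line)
#' @slot config the [SimulationConfig-class] used
#' @export
setClass("GroundTruth",
  representation(latMs = "matrix", beatTimesMs = "numeric",
                 tissueLat = "list", blockLines = "data.frame",
                 cbExpected = "data.frame", expectedType = "matrix",
                 config = "SimulationConfig"))

#' @export
setMethod("latMatrix", "GroundTruth", function(x) x@latMs)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %dx%d electrode LATs, %d beat(s), %d block line(s), %d expected CB pair(s)\n",
    nrow(object@latMs), ncol(object@latMs), length(object@beatTimesMs),
    nrow(object@blockLines), nrow(object@cbExpected)))
})
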