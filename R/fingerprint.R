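#' @include AllClasses.R
NULL

#' Run the full per-site analysis pipeline
#'
#' Segments beats on the reference channel, estimates per-channel noise,
#' detects deflections and annotates LATs for every included electrode and
#' accepted beat, classifies each electrode-beat potential, and builds one
#' activation map per accepted beat (with simultaneous-activation exclusion
#' and conduction-block detection applied).
#'
#' @param site a [SiteRecording-class]
#' @param params an [AnalysisParams-class]
#' @param patientIdLabel patient label copied into the potential table
#' @return list with elements:
#'   \describe{
#'     \item{potentials}{data.frame, one row per classified electrode-beat
#'       (the columns of [writePotentialTable()])}
#'     \item{maps}{list of [ActivationMap-class], one per accepted beat}
#'     \item{beats}{beat window table from [segmentBeats()]}
#'     \item{counts}{named counts: electrode-beats analyzed, without
#'       potential, excluded channels, rejected beats}
#'   }
#' @export
analyzeSite <- function(site, params = AnalysisParams(),
                        patientIdLabel = "") {
  stopifnot(is(site, "SiteRecording"))
  validObject(site)
  arr <- electrodeGrid(site)
  nr <- nRows(arr); nc <- nCols(arr)
  fs <- samplingRate(site)
  beats <- segmentBeats(referenceTrace(site), fs, params)
  acc <- which(beats$accepted)
  sig <- signals(site)
  quality <- channelQuality(site)
  rows <- vector("list", 0L)
  latArr <- array(NA_real_, dim = c(nr, nc, length(acc)))
  nNoPotential <- 0L
  for (e in seq_len(nr * nc)) {
    if (!quality[e]) next
    trace <- sig[e, ]
    noise <- tryCatch(estimateNoise(trace, beats, fs),
                      error = function(err) NULL)
    if (is.null(noise)) next   # flat channel: nothing to annotate
    rc <- .idxToRowCol(e, nc)
    for (bi in seq_along(acc)) {
      b <- acc[bi]
      defl <- detectDeflections(trace, beats[b, ], noise, params, fs)
      if (nrow(defl) == 0L) {
        nNoPotential <- nNoPotential + 1L
        next
      }
      type <- classifyPotential(defl, params)
      lat <- annotateLat(defl)
      pp <- peakToPeak(defl, params)
      latArr[rc[1L], rc[2L], bi] <- lat
      rs <- if (type == "SP") rsRatio(defl$r_mv[1L], defl$s_mv[1L])
            else NA_real_
      fd <- if (type == "SP") 0 else fractionationDuration(defl)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patientIdLabel, region = region(site),
        site_id = siteId(site), row = rc[1L], col = rc[2L], beat = b,
        type = type, lat_ms = lat, r_mv = max(defl$r_mv),
        s_mv = max(defl$s_mv), rs_ratio = rs, vpp_mv = pp$vpp_mv,
        low_voltage = pp$low_voltage, fd_ms = fd,
        n_deflections = nrow(defl),
        deflection_times_ms = paste(.fmtNum(defl$t_ms), collapse = ";"))
    }
  }
  potentials <- if (length(rows)) do.call(rbind, rows) else .emptyPotentials()
  maps <- lapply(seq_along(acc), function(bi) {
    m <- buildActivationMap(site, matrix(latArr[, , bi], nr, nc),
                            beat = acc[bi])
    m <- excludeSimultaneousAreas(m, params)
    suppressWarnings(detectConductionBlock(m, params))
  })
  counts <- c(analyzed = nrow(potentials), no_potential = nNoPotential,
              excluded_channels = sum(!quality),
              rejected_beats = sum(!beats$accepted))
  list(potentials = potentials, maps = maps, beats = beats, counts = counts)
}

.emptyPotentials <- function() {
  data.frame(patient_id = character(), region = character(),
             site_id = character(), row = integer(), col = integer(),
             beat = integer(), type = character(), lat_ms = numeric(),
             r_mv = numeric(), s_mv = numeric(), rs_ratio = numeric(),
             vpp_mv = numeric(), low_voltage = logical(), fd_ms = numeric(),
             n_deflections = integer(), deflection_times_ms = character())
}

## histogram bin design (see vignette): voltage 0.5 mV bins on [0, 20],
## R/S 0.05 bins on [-1, 1], FD 1 ms bins on [0, 60]; stacked by type
.fpBreaks <- list(voltage = seq(0, 20, by = 0.5),
                  rs = seq(-1, 1, by = 0.05),
                  fd = seq(0, 60, by = 1))

#' Summarize one region of the fingerprint
#'
#' Aggregates classified potentials and per-beat activation maps of one
#' region into a [RegionFingerprint-class]: medians over all pooled
#' electrode-beats (R/S over single potentials only; FD over
#' multi-deflection potentials), type proportions, the low-voltage
#' percentage, the pooled conduction-block percentage (total block edges
#' over total evaluable pairs of all maps), and the stacked relative
#' frequency distributions.
#'
#' @param potentials potential table rows of this region
#' @param maps list of [ActivationMap-class] of the region's sites
#' @param regionLabel region label stored in the result (\code{"ALL"} for
#'   the pooled entry)
#' @return a [RegionFingerprint-class]
#' @export
summarizeRegion <- function(potentials, maps, regionLabel) {
  n <- nrow(potentials)
  histos <- list()
  if (n == 0L) {
    return(new("RegionFingerprint", region = regionLabel, nPotentials = 0L,
               medianVoltageMv = NA_real_, pctLowVoltage = NA_real_,
               medianRsRatio = NA_real_, pctSp = NA_real_,
               pctSdp = NA_real_, pctLdp = NA_real_, pctFp = NA_real_,
               medianFdMs = NA_real_, pctCb = .pooledCb(maps),
               histograms = list()))
  }
  counts <- vapply(POTENTIAL_TYPES, function(tp) sum(potentials$type == tp),
                   numeric(1))
  pct <- 100 * counts / n
  sp <- potentials[potentials$type == "SP", ]
  multi <- potentials[potentials$type != "SP", ]
  voltHist <- vapply(POTENTIAL_TYPES, function(tp)
    .histCounts(potentials$vpp_mv[potentials$type == tp],
                .fpBreaks$voltage), integer(length(.fpBreaks$voltage) - 1L))
  rsHist <- .histCounts(sp$rs_ratio, .fpBreaks$rs)
  fdHist <- vapply(c("SDP", "LDP", "FP"), function(tp)
    .histCounts(potentials$fd_ms[potentials$type == tp], .fpBreaks$fd),
    integer(length(.fpBreaks$fd) - 1L))
  histos <- list(
    voltage = list(breaks = .fpBreaks$voltage, counts = t(voltHist)),
    rs = list(breaks = .fpBreaks$rs,
              counts = matrix(rsHist, nrow = 1L,
                              dimnames = list("SP", NULL))),
    fd = list(breaks = .fpBreaks$fd, counts = t(fdHist)))
  new("RegionFingerprint", region = regionLabel, nPotentials = as.integer(n),
      medianVoltageMv = stats::median(potentials$vpp_mv),
      pctLowVoltage = 100 * mean(potentials$low_voltage),
      medianRsRatio = if (nrow(sp)) stats::median(sp$rs_ratio) else NA_real_,
      pctSp = pct[["SP"]], pctSdp = pct[["SDP"]], pctLdp = pct[["LDP"]],
      pctFp = pct[["FP"]],
      medianFdMs = if (nrow(multi)) stats::median(multi$fd_ms) else NA_real_,
      pctCb = .pooledCb(maps), histograms = histos)
}

.pooledCb <- function(maps) {
  if (length(maps) == 0L) return(NA_real_)
  blocked <- sum(vapply(maps, function(m) nrow(m@cbEdges), numeric(1)))
  evaluable <- sum(vapply(maps, function(m)
    ifelse(is.na(m@evaluablePairs), 0L, m@evaluablePairs), integer(1)))
  if (evaluable == 0L) NA_real_ else 100 * blocked / evaluable
}

#' Build the per-patient signal fingerprint
#'
#' Runs [analyzeSite()] on every site of a dataset and aggregates the
#' classified potentials and conduction-block maps into one
#' [RegionFingerprint-class] per mapped region plus a pooled entry over
#' the entire atrium (every potential weighted equally). Deterministic for
#' a fixed dataset and parameter set.
#'
#' @param dataset a [PatientDataset-class]
#' @param params an [AnalysisParams-class]
#' @return a [PatientFingerprint-class]
#' @export
buildFingerprint <- function(dataset, params = AnalysisParams()) {
  stopifnot(is(dataset, "PatientDataset"))
  allPot <- list(); allMaps <- list(); mapRegion <- character()
  for (k in seq_along(dataset@sites)) {
    s <- dataset@sites[[k]]
    res <- tryCatch(analyzeSite(s, params, patientIdLabel = patientId(dataset)),
                    error = function(err)
                      .stopf("site '%s' (%s): %s", siteId(s), region(s),
                             conditionMessage(err)))
    allPot[[k]] <- res$potentials
    allMaps[[k]] <- res$maps
    mapRegion <- c(mapRegion, rep(region(s), length(res$maps)))
  }
  potentials <- if (length(allPot)) do.call(rbind, allPot)
                else .emptyPotentials()
  maps <- do.call(c, c(allMaps, list(list())))
  regionsPresent <- REGIONS[REGIONS %in%
    vapply(dataset@sites, region, character(1))]
  regFps <- lapply(regionsPresent, function(reg)
    summarizeRegion(potentials[potentials$region == reg, , drop = FALSE],
                    maps[mapRegion == reg], reg))
  names(regFps) <- regionsPresent
  overall <- summarizeRegion(potentials, maps, "ALL")
  burden <- if (overall@nPotentials > 0L) overall@pctLdp + overall@pctFp
            else NA_real_
  new("PatientFingerprint", patientId = patientId(dataset),
      regions = regFps, overall = overall, paramsEcho = paramsAsList(params),
      ldpFpBurden = burden,
      pipelineVersion = as.character(utils::packageVersion("egmprint")))
}

#' Per-electrode signal map
#'
#' For every electrode of a site, the fraction of accepted beats yielding
#' each potential type (the per-site "signal map" of type proportions).
#' Electrodes without any classified beat are absent from the result;
#' fractions of present electrodes sum to 1.
#'
#' @param potentials potential table of one site (from [analyzeSite()])
#' @return data.frame with columns \code{row}, \code{col}, \code{n_beats},
#'   \code{f_sp}, \code{f_sdp}, \code{f_ldp}, \code{f_fp}
#' @export
signalMap <- function(potentials) {
  if (nrow(potentials) == 0L)
    return(data.frame(row = integer(), col = integer(), n_beats = integer(),
                      f_sp = numeric(), f_sdp = numeric(), f_ldp = numeric(),
                      f_fp = numeric()))
  key <- interaction(potentials$row, potentials$col, drop = TRUE)
  out <- do.call(rbind, lapply(split(potentials, key), function(d) {
    nb <- nrow(d)
    data.frame(row = d$row[1L], col = d$col[1L], n_beats = nb,
               f_sp = sum(d$type == "SP") / nb,
               f_sdp = sum(d$type == "SDP") / nb,
               f_ldp = sum(d$type == "LDP") / nb,
               f_fp = sum(d$type == "FP") / nb)
  }))
  rownames(out) <- NULL
  out[order(out$row, out$col), , drop = FALSE]
}

#' Rank patients by fractionation burden
#'
#' Orders fingerprints by ascending pooled LDP+FP percentage; ties are
#' broken by patient id (lexicographic), so the ranking is stable.
#'
#' @param fingerprints list of [PatientFingerprint-class]
#' @return the list, reordered
#' @export
rankPatients <- function(fingerprints) {
  stopifnot(length(fingerprints) >= 1L)
  burdens <- vapply(fingerprints, ldpFpBurden, numeric(1))
  ids <- vapply(fingerprints, patientId, character(1))
  fingerprints[order(burdens, ids)]
}

## ------------------------------------------------------------- document --

.regionFpAsList <- function(fp) {
  out <- list(region = fp@region, n_potentials = fp@nPotentials,
              median_voltage_mv = fp@medianVoltageMv,
              pct_low_voltage = fp@pctLowVoltage,
              median_rs_ratio = fp@medianRsRatio,
              pct_sp = fp@pctSp, pct_sdp = fp@pctSdp, pct_ldp = fp@pctLdp,
              pct_fp = fp@pctFp, median_fd_ms = fp@medianFdMs,
              pct_cb = fp@pctCb)
  if (length(fp@histograms)) {
    out$histograms <- lapply(fp@histograms, function(h)
      list(breaks = h$breaks,
           counts = lapply(seq_len(nrow(h$counts)), function(i)
             as.integer(h$counts[i, ])),
           types = rownames(h$counts)))
    names(out$histograms) <- names(fp@histograms)
  }
  out
}

.regionFpFromList <- function(x) {
  histos <- list()
  if (!is.null(x$histograms)) {
    histos <- lapply(x$histograms, function(h) {
      cm <- do.call(rbind, lapply(h$counts, as.integer))
      rownames(cm) <- h$types
      list(breaks = as.numeric(h$breaks), counts = cm)
    })
    names(histos) <- names(x$histograms)
  }
  naify <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("RegionFingerprint", region = x$region,
      nPotentials = as.integer(x$n_potentials),
      medianVoltageMv = naify(x$median_voltage_mv),
      pctLowVoltage = naify(x$pct_low_voltage),
      medianRsRatio = naify(x$median_rs_ratio), pctSp = naify(x$pct_sp),
      pctSdp = naify(x$pct_sdp), pctLdp = naify(x$pct_ldp),
      pctFp = naify(x$pct_fp), medianFdMs = naify(x$median_fd_ms),
      pctCb = naify(x$pct_cb), histograms = histos)
}

#' Write a fingerprint document
#'
#' Structured key-value YAML containing all regional and pooled scalars,
#' histogram arrays, the parameter echo and the pipeline version. Writing
#' is deterministic: the same fingerprint always produces a byte-identical
#' file.
#'
#' @param fingerprint a [PatientFingerprint-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeFingerprint <- function(fingerprint, path) {
  stopifnot(is(fingerprint, "PatientFingerprint"))
  doc <- list(
    format = "egmprint-fingerprint", format_version = 1L,
    pipeline_version = fingerprint@pipelineVersion,
    patient_id = fingerprint@patientId,
    ldp_fp_burden = fingerprint@ldpFpBurden,
    params = fingerprint@paramsEcho,
    overall = .regionFpAsList(fingerprint@overall),
    regions = lapply(fingerprint@regions, .regionFpAsList))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read a fingerprint document
#'
#' @param path file written by [writeFingerprint()]
#' @return a [PatientFingerprint-class]
#' @export
readFingerprint <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$format) || x$format != "egmprint-fingerprint")
    .stopf("'%s' is not a fingerprint document", path)
  regs <- lapply(x$regions, .regionFpFromList)
  new("PatientFingerprint", patientId = x$patient_id, regions = regs,
      overall = .regionFpFromList(x$overall), paramsEcho = x$params,
      ldpFpBurden = if (is.null(x$ldp_fp_burden)) NA_real_
                    else as.numeric(x$ldp_fp_burden),
      pipelineVersion = x$pipeline_version)
}
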