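#' @include AllClasses.R
NULL

## Recording bundle: one directory per patient.
##   manifest.json            patient id, metadata, per-site entries
##   sites/<id>_signals.bin   float32 little-endian, electrode-major
##   sites/<id>_reference.bin float32 little-endian
## Voltages are stored in millivolts as 32-bit floats; the manifest is
## written with a fixed key order so two writes of the same dataset are
## byte-identical.

#' Write a recording bundle
#'
#' Serializes a [PatientDataset-class] into the package's bundle format: a
#' directory with a JSON manifest (grid shape, spacing, region, sampling
#' rate, electrode ids, channel-quality flags per site) and little-endian
#' float32 payloads for signals and reference traces. Lossless for voltages
#' at float32 precision, and deterministic: writing the same dataset twice
#' yields byte-identical files.
#'
#' @param dataset a [PatientDataset-class]
#' @param path bundle directory (created; existing manifest/payloads are
#'   overwritten)
#' @return \code{path}, invisibly
#' @seealso [readRecordingBundle()]
#' @export
writeRecordingBundle <- function(dataset, path) {
  stopifnot(is(dataset, "PatientDataset"))
  validObject(dataset)
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    .stopf("cannot create bundle directory '%s'", path)
  dir.create(file.path(path, "sites"), showWarnings = FALSE)
  siteEntries <- lapply(seq_along(dataset@sites), function(k) {
    s <- dataset@sites[[k]]
    arr <- electrodeGrid(s)
    id <- siteId(s)
    sigFile <- file.path("sites", paste0(id, "_signals.bin"))
    refFile <- file.path("sites", paste0(id, "_reference.bin"))
    con <- file(file.path(path, sigFile), "wb")
    writeBin(as.numeric(t(signals(s))), con, size = 4L, endian = "little")
    close(con)
    con <- file(file.path(path, refFile), "wb")
    writeBin(as.numeric(referenceTrace(s)), con, size = 4L,
             endian = "little")
    close(con)
    list(site_id = id, region = region(s), n_rows = nRows(arr),
         n_cols = nCols(arr), spacing_mm = spacingMm(arr),
         electrode_ids = electrodeIds(arr), fs_hz = samplingRate(s),
         n_samples = ncol(signals(s)),
         channel_quality = channelQuality(s),
         signals_file = sigFile, reference_file = refFile)
  })
  manifest <- list(format = "egmprint-bundle", format_version = 1L,
                   patient_id = patientId(dataset),
                   metadata = metadata(dataset), sites = siteEntries)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(path, "manifest.json"))
  invisible(path)
}

#' Read a recording bundle
#'
#' @param path bundle directory written by [writeRecordingBundle()]
#' @return a [PatientDataset-class]
#' @export
readRecordingBundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    .stopf("'%s' is not a recording bundle (manifest.json missing)", path)
  manifest <- jsonlite::fromJSON(mf, simplifyDataFrame = FALSE,
                                 simplifyVector = TRUE)
  if (is.null(manifest$patient_id) || is.null(manifest$sites))
    .stopf("bundle manifest is malformed: patient_id or sites missing")
  sitesList <- lapply(manifest$sites, function(e) {
    req <- c("site_id", "region", "n_rows", "n_cols", "spacing_mm",
             "fs_hz", "n_samples", "signals_file", "reference_file")
    miss <- req[!req %in% names(e)]
    if (length(miss))
      .stopf("bundle site entry is missing grid metadata: %s",
             paste(miss, collapse = ", "))
    if (!(e$region %in% REGIONS))
      .stopf("region '%s' invalid for site '%s'; allowed regions: %s",
             e$region, e$site_id, paste(REGIONS, collapse = ", "))
    nel <- as.integer(e$n_rows) * as.integer(e$n_cols)
    ns <- as.integer(e$n_samples)
    sig <- .readFloat32(file.path(path, e$signals_file), nel * ns)
    sig <- matrix(sig, nrow = nel, ncol = ns, byrow = TRUE)
    ref <- .readFloat32(file.path(path, e$reference_file), ns)
    quality <- if (!is.null(e$channel_quality)) as.logical(e$channel_quality)
               else rep(TRUE, nel)
    bad <- which(quality)[!apply(is.finite(
      sig[which(quality), , drop = FALSE]), 1L, all)]
    if (length(bad))
      .stopf("non-finite samples on included channel %d of site '%s'",
             bad[1L], e$site_id)
    arr <- ElectrodeArray(e$n_rows, e$n_cols, e$spacing_mm,
                          electrodeIds = e$electrode_ids)
    SiteRecording(arr, e$region, sig, fsHz = e$fs_hz, reference = ref,
                  channelQuality = quality, siteId = e$site_id)
  })
  PatientDataset(manifest$patient_id, sitesList,
                 metadata = if (is.null(manifest$metadata)) list()
                            else manifest$metadata)
}

.readFloat32 <- function(file, n) {
  if (!file.exists(file)) .stopf("bundle payload '%s' missing", file)
  con <- file(file, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n, size = 4L, endian = "little")
  if (length(x) != n)
    .stopf("bundle payload '%s' truncated (%d of %d values)", file,
           length(x), n)
  x
}

## fixed column order of the potential table
.potentialTableCols <- c("patient_id", "region", "site_id", "row", "col",
                         "beat", "type", "lat_ms", "r_mv", "s_mv",
                         "rs_ratio", "vpp_mv", "low_voltage", "fd_ms",
                         "deflection_times_ms")

#' Write the classified-potential table
#'
#' One CSV row per classified potential (electrode-beat) with the fixed
#' header \code{patient_id,region,site_id,row,col,beat,type,lat_ms,r_mv,
#' s_mv,rs_ratio,vpp_mv,low_voltage,fd_ms,deflection_times_ms}; deflection
#' times are \code{;}-joined. Numeric values are printed with 12
#' significant digits so a re-parsed table agrees to well below 1e-9.
#'
#' @param potentials potential table as produced by [analyzeSite()] /
#'   [buildFingerprint()]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writePotentialTable <- function(potentials, path) {
  df <- potentials[, .potentialTableCols, drop = FALSE]
  lines <- c(paste(.potentialTableCols, collapse = ","))
  if (nrow(df)) {
    body <- vapply(seq_len(nrow(df)), function(i) {
      paste(c(df$patient_id[i], df$region[i], df$site_id[i],
              df$row[i], df$col[i], df$beat[i], df$type[i],
              .fmtNum(df$lat_ms[i]), .fmtNum(df$r_mv[i]),
              .fmtNum(df$s_mv[i]), .fmtNum(df$rs_ratio[i]),
              .fmtNum(df$vpp_mv[i]), tolower(df$low_voltage[i]),
              .fmtNum(df$fd_ms[i]), df$deflection_times_ms[i]),
            collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a potential table
#'
#' @param path file written by [writePotentialTable()]
#' @return data.frame with the documented columns
#' @export
readPotentialTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(deflection_times_ms = "character"))
  if (!identical(names(df), .potentialTableCols))
    .stopf("'%s' does not have the potential-table header", path)
  df$low_voltage <- as.logical(toupper(df$low_voltage))
  df
}
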