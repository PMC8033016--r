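#' Atrial regions covered by the mapping scheme
#'
#' Region codes used throughout the package: right atrium (RA), Bachmann's
#' bundle (BB), pulmonary vein area (PVA) and left atrium (LA).
#'
#' @export
REGIONS <- c("RA", "BB", "PVA", "LA")

#' Potential type labels
#'
#' SP = single potential (one negative deflection), SDP/LDP = short/long
#' double potential (two deflections, split at the SDP/LDP boundary),
#' FP = fractionated potential (three or more deflections).
#'
#' @export
POTENTIAL_TYPES <- c("SP", "SDP", "LDP", "FP")

## evaluate `code` under a fixed RNG state without disturbing the caller's
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

## round-trip a numeric vector/matrix through IEEE float32 so that values
## written to a bundle read back bit-for-bit identical
.asFloat32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               what = "double", n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

## 5-point quadratic Savitzky-Golay first derivative (mV/ms); the two edge
## samples on each side have no defined slope
.slopeSeries <- function(x, dtMs) {
  n <- length(x)
  s <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    s[i] <- (-2 * x[i - 2] - x[i - 1] + x[i + 1] + 2 * x[i + 2]) / (10 * dtMs)
  }
  s
}

## histogram counts with out-of-range values clamped into the edge bins so
## counts always sum to length(values)
.histCounts <- function(values, breaks) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    return(integer(length(breaks) - 1L))
  }
  lo <- breaks[1L]
  hi <- breaks[length(breaks)]
  eps <- (hi - lo) * 1e-9
  values <- pmin(pmax(values, lo + eps), hi - eps)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}

## electrode index (row-major, 1-based) <-> (row, col)
.idxToRowCol <- function(idx, nCols) {
  cbind(row = (idx - 1L) %/% nCols + 1L, col = (idx - 1L) %% nCols + 1L)
}

.rowColToIdx <- function(row, col, nCols) {
  (row - 1L) * nCols + col
}

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
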