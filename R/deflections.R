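#' @include AllClasses.R
NULL

#' Segment beats on the reference channel
#'
#' Detects beat fiducials as local maxima of the reference trace above half
#' its peak amplitude, builds one analysis window per beat
#' (\code{-beatPreMs / +beatPostMs} around the fiducial, clipped to the
#' recording and to the midpoints between fiducials so windows never
#' overlap), and rejects premature beats: a beat whose preceding cycle
#' length is shorter than \code{prematureBeatFraction} times the median
#' cycle length is marked not accepted.
#'
#' @param reference numeric reference trace
#' @param fsHz sampling rate (Hz)
#' @param params an [AnalysisParams-class]
#' @return data.frame with columns \code{start_ms}, \code{end_ms},
#'   \code{reference_time_ms}, \code{accepted}; zero rows (with a warning)
#'   when no beat is found
#' @examples
#' ref <- numeric(5000)
#' ref[c(500, 1500, 2500, 3500, 4500)] <- 1
#' segmentBeats(ref, 1000, AnalysisParams())
#' @export
segmentBeats <- function(reference, fsHz, params = AnalysisParams()) {
  stopifnot(is.numeric(reference), fsHz > 0)
  dtMs <- 1000 / fsHz
  n <- length(reference)
  peak <- max(reference)
  if (!is.finite(peak) || peak <= 0) {
    .warnf("no beats detected on the reference channel")
    return(.emptyBeats())
  }
  thr <- 0.5 * peak
  x <- reference
  ## local maxima above threshold
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  if (length(cand) == 0L) {
    .warnf("no beats detected on the reference channel")
    return(.emptyBeats())
  }
  ## collapse plateaus / ringing within a 150 ms refractory: keep largest
  keep <- integer()
  refractory <- 150 / dtMs
  for (i in cand) {
    if (length(keep) && (i - keep[length(keep)]) < refractory) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  tFid <- (keep - 1) * dtMs
  nb <- length(tFid)
  accepted <- rep(TRUE, nb)
  if (nb >= 2L) {
    cycles <- diff(tFid)
    medCycle <- stats::median(cycles)
    accepted[-1L] <- cycles >= params@prematureBeatFraction * medCycle
  }
  start <- pmax(tFid - params@beatPreMs, 0)
  end <- pmin(tFid + params@beatPostMs, (n - 1) * dtMs)
  if (nb >= 2L) {
    mid <- (tFid[-nb] + tFid[-1L]) / 2
    end[-nb] <- pmin(end[-nb], mid)
    start[-1L] <- pmax(start[-1L], mid)
  }
  data.frame(start_ms = start, end_ms = end, reference_time_ms = tFid,
             accepted = accepted)
}

.emptyBeats <- function() {
  data.frame(start_ms = numeric(), end_ms = numeric(),
             reference_time_ms = numeric(), accepted = logical())
}

#' Estimate the noise level of one channel
#'
#' Robust noise sigma from the quiescent samples between beat windows:
#' median absolute deviation scaled by 1.4826 (consistent for a Gaussian).
#' When no quiescent samples are available the whole trace is used, with a
#' warning. A constant trace has no defined noise level and is an error
#' (degenerate signal).
#'
#' @param trace single-channel voltage series (mV)
#' @param windows beat windows from [segmentBeats()]
#' @param fsHz sampling rate (Hz)
#' @return a [NoiseEstimate-class]
#' @export
estimateNoise <- function(trace, windows, fsHz = 1000) {
  stopifnot(is.numeric(trace))
  if (length(trace) == 0L || all(trace == trace[1L]))
    .stopf("degenerate signal: trace is constant, noise level undefined")
  dtMs <- 1000 / fsHz
  quiet <- rep(TRUE, length(trace))
  if (NROW(windows) > 0L) {
    for (k in seq_len(nrow(windows))) {
      i0 <- max(1L, floor(windows$start_ms[k] / dtMs) + 1L)
      i1 <- min(length(trace), ceiling(windows$end_ms[k] / dtMs) + 1L)
      quiet[i0:i1] <- FALSE
    }
  }
  method <- "mad-quiescent"
  q <- trace[quiet]
  if (length(q) < 50L) {
    .warnf("no quiescent samples between beats; using the whole trace")
    q <- trace
    method <- "mad-global"
  }
  sigma <- stats::mad(q)
  if (sigma <= 0) {
    ## quiescent segments exactly flat (e.g. noise-free synthesis): fall
    ## back to a vanishing but positive spread so downstream gating (which
    ## applies the analysis noise floor) stays defined
    sigma <- max(stats::mad(trace), .Machine$double.eps)
    method <- "mad-global-floor"
  }
  NoiseEstimate(sigma, method)
}

#' Detect negative deflections within one beat window
#'
#' Candidate deflections are local minima of the band-limited first
#' derivative (5-point Savitzky-Golay) falling below a noise-scaled negative
#' slope threshold. Candidates closer than
#' \code{minDeflectionSeparationMs} are merged, keeping the steeper one.
#' For each surviving candidate the R-wave amplitude is the local maximum
#' preceding the downstroke and the S-wave amplitude the local minimum
#' following it, both relative to the window baseline (median of the window
#' edges) and bounded by the midpoints to neighbouring candidates. A
#' deflection is retained only if its peak-to-peak amplitude reaches
#' \code{snrFactor} times the noise sigma (floored at \code{noiseFloorMv}).
#'
#' @param trace single-channel voltage series (mV)
#' @param window one beat window (list or one-row data.frame with
#'   \code{start_ms}, \code{end_ms})
#' @param noise a [NoiseEstimate-class]
#' @param params an [AnalysisParams-class]
#' @param fsHz sampling rate (Hz)
#' @return data.frame with one row per deflection, time-ordered:
#'   \code{t_ms} (absolute time of steepest negative slope),
#'   \code{slope_mv_per_ms} (< 0), \code{r_mv}, \code{s_mv}, \code{vpp_mv}
#' @export
detectDeflections <- function(trace, window, noise, params = AnalysisParams(),
                              fsHz = 1000) {
  stopifnot(is(noise, "NoiseEstimate"))
  dtMs <- 1000 / fsHz
  i0 <- max(1L, floor(window$start_ms[1L] / dtMs) + 1L)
  i1 <- min(length(trace), floor(window$end_ms[1L] / dtMs) + 1L)
  if (i1 - i0 + 1L < 7L) return(.emptyDeflections())
  x <- trace[i0:i1]
  if (params@applyBandpass)
    x <- bandpassFilter(x, fsHz, params@bandpassLowHz, params@bandpassHighHz)
  m <- length(x)
  slope <- .slopeSeries(x, dtMs)
  sigma <- max(noise@sigmaMv, params@noiseFloorMv)
  ## white-noise sd propagated through the SG derivative: sigma*sqrt(10)/10/dt
  slopeThr <- -params@slopeGateFactor * sigma * sqrt(10) / 10 / dtMs
  ok <- which(!is.na(slope) & slope < slopeThr)
  ok <- ok[ok > 3L & ok < m - 2L]
  cand <- ok[slope[ok] <= slope[ok - 1L] & slope[ok] <= slope[ok + 1L]]
  ## collapse runs of equal slope (flat minima): keep the first sample
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, diff(cand) > 1L | diff(slope[cand]) != 0)]
  if (length(cand) == 0L) return(.emptyDeflections())
  ## merge candidates closer than the separation limit, keep the steeper
  minSep <- params@minDeflectionSeparationMs / dtMs
  repeat {
    if (length(cand) < 2L) break
    gaps <- diff(cand)
    j <- which(gaps < minSep)
    if (length(j) == 0L) break
    j <- j[1L]
    drop <- if (slope[cand[j]] <= slope[cand[j + 1L]]) j + 1L else j
    cand <- cand[-drop]
  }
  baseline <- stats::median(c(utils::head(x, 5L), utils::tail(x, 5L)))
  ## neighbourhood bounds: midpoints between consecutive candidates
  nb <- length(cand)
  lo <- c(1L, floor((cand[-nb] + cand[-1L]) / 2))
  hi <- c(ceiling((cand[-nb] + cand[-1L]) / 2), m)
  r <- s <- numeric(nb)
  for (k in seq_len(nb)) {
    pre <- x[lo[k]:cand[k]]
    post <- x[cand[k]:hi[k]]
    r[k] <- max(0, max(pre) - baseline)
    s[k] <- max(0, baseline - min(post))
  }
  vpp <- r + s
  keep <- vpp >= params@snrFactor * sigma
  if (!any(keep)) return(.emptyDeflections())
  data.frame(
    t_ms = (i0 + cand[keep] - 2L) * dtMs,
    slope_mv_per_ms = slope[cand[keep]],
    r_mv = r[keep], s_mv = s[keep], vpp_mv = vpp[keep]
  )
}

.emptyDeflections <- function() {
  data.frame(t_ms = numeric(), slope_mv_per_ms = numeric(),
             r_mv = numeric(), s_mv = numeric(), vpp_mv = numeric())
}

#' Annotate the local activation time
#'
#' The LAT of a unipolar electrogram is the time of its steepest negative
#' slope, i.e. the deflection with the most negative \code{slope_mv_per_ms}.
#'
#' @param deflections deflection table from [detectDeflections()]
#' @return LAT in ms, or \code{NA_real_} when no deflection is present
#' @examples
#' d <- data.frame(t_ms = c(30, 42), slope_mv_per_ms = c(-2, -5),
#'                 r_mv = 1, s_mv = 1, vpp_mv = 2)
#' annotateLat(d)  # 42
#' @export
annotateLat <- function(deflections) {
  if (NROW(deflections) == 0L) return(NA_real_)
  deflections$t_ms[which.min(deflections$slope_mv_per_ms)]
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero phase), mirroring the acquisition bandwidth of the mapping system.
#'
#' @param x numeric trace
#' @param fsHz sampling rate (Hz)
#' @param lowHz,highHz band edges (Hz); \code{highHz} is clipped below the
#'   Nyquist frequency
#' @return filtered trace
#' @export
bandpassFilter <- function(x, fsHz, lowHz = 0.5, highHz = 400) {
  nyq <- fsHz / 2
  highHz <- min(highHz, 0.99 * nyq)
  bf <- signal::butter(2, c(lowHz, highHz) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}
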