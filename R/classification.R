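#' @include AllClasses.R
NULL

#' Classify a potential by its deflection count and spacing
#'
#' One deflection is a single potential (SP). Two deflections form a double
#' potential: short (SDP) when the interval between the deflections is below
#' the SDP/LDP boundary (15 ms by default), long (LDP) when the interval is
#' at or above it. Three or more deflections form a fractionated potential
#' (FP), regardless of spacing.
#'
#' @param deflections a deflection table from [detectDeflections()] or a
#'   numeric vector of deflection times (ms)
#' @param params an [AnalysisParams-class]
#' @return \code{"SP"}, \code{"SDP"}, \code{"LDP"} or \code{"FP"};
#'   \code{NA_character_} for an empty input (no potential: the
#'   electrode-beat is excluded from type proportions)
#' @examples
#' classifyPotential(c(40, 50))   # SDP (10 ms interval)
#' classifyPotential(c(40, 55))   # LDP (interval exactly at the boundary)
#' classifyPotential(c(40, 48, 70))  # FP
#' @export
classifyPotential <- function(deflections, params = AnalysisParams()) {
  times <- if (is.data.frame(deflections)) deflections$t_ms else deflections
  n <- length(times)
  if (n == 0L) return(NA_character_)
  if (is.unsorted(times)) times <- sort(times)
  if (n >= params@fpMinDeflections) return("FP")
  if (n == 1L) return("SP")
  ## exactly two deflections
  if (times[2L] - times[1L] < params@sdpLdpBoundaryMs) "SDP" else "LDP"
}

#' Fractionation duration
#'
#' Time difference between the first and the last deflection of a
#' potential, in ms. Zero for a single deflection. Computed for every
#' multi-deflection type (SDP, LDP, FP) so that per-type FD distributions
#' can be reported.
#'
#' @inheritParams classifyPotential
#' @return FD in ms (0 for an SP, \code{NA} for an empty input)
#' @examples
#' fractionationDuration(c(40, 48, 70))  # 30
#' @export
fractionationDuration <- function(deflections) {
  times <- if (is.data.frame(deflections)) deflections$t_ms else deflections
  if (length(times) == 0L) return(NA_real_)
  max(times) - min(times)
}

#' Signed R/S ratio of a single potential
#'
#' Maps the relative R- and S-wave amplitudes of a single potential onto
#' \eqn{[-1, 1]}: with \eqn{q = R/S}, the ratio is \eqn{1 - q} for
#' \eqn{q \le 1} and \eqn{1/q - 1} for \eqn{q > 1}. A potential consisting
#' solely of an S-wave (R = 0) scores +1; solely an R-wave (S = 0) scores
#' -1 (the continuous limits of the piecewise formula). Vectorized.
#'
#' @param r_mv R-wave amplitude(s), mV, \eqn{\ge 0}
#' @param s_mv S-wave amplitude(s), mV, \eqn{\ge 0}
#' @return ratio value(s) in \eqn{[-1, 1]}
#' @examples
#' rsRatio(1, 2)    #  0.5
#' rsRatio(2, 1)    # -0.5
#' rsRatio(0, 1.3)  #  1
#' rsRatio(0.8, 0)  # -1
#' @export
rsRatio <- function(r_mv, s_mv) {
  if (length(r_mv) != length(s_mv))
    .stopf("r_mv and s_mv must have the same length")
  if (any(r_mv < 0 | s_mv < 0, na.rm = TRUE))
    .stopf("amplitudes must be non-negative")
  if (any(r_mv + s_mv == 0, na.rm = TRUE))
    .stopf("R and S amplitudes are both zero: R/S ratio undefined")
  q <- r_mv / s_mv                    # Inf when s = 0, 0 when r = 0
  out <- ifelse(q <= 1, 1 - q, 1 / q - 1)
  out[r_mv == 0] <- 1
  out[s_mv == 0] <- -1
  out
}

#' Peak-to-peak amplitude and low-voltage flag of a potential
#'
#' The peak-to-peak voltage of a potential is the largest R-wave extremum
#' plus the largest S-wave magnitude over all of its deflections (i.e. the
#' global excursion over the beat window). A potential is low-voltage when
#' its amplitude is strictly below the cut-off (1.0 mV by default; an
#' amplitude of exactly 1.0 mV is not low-voltage).
#'
#' @param deflections deflection table from [detectDeflections()]
#' @param params an [AnalysisParams-class]
#' @return list with \code{vpp_mv} and \code{low_voltage}
#' @examples
#' d <- data.frame(t_ms = 40, slope_mv_per_ms = -2, r_mv = 0.4, s_mv = 0.5,
#'                 vpp_mv = 0.9)
#' peakToPeak(d)  # vpp 0.9, low_voltage TRUE
#' @export
peakToPeak <- function(deflections, params = AnalysisParams()) {
  if (NROW(deflections) == 0L)
    .stopf("peakToPeak requires at least one deflection")
  vpp <- max(deflections$r_mv) + max(deflections$s_mv)
  list(vpp_mv = vpp, low_voltage = vpp < params@lowVoltageMv)
}
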