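#' @include AllClasses.R
NULL

## ----------------------------------------------------------- LAT fields --

## tissue lattice geometry for a config: node coordinates (mm) with the
## electrode positions guaranteed to be lattice points
.tissueLattice <- function(config) {
  sp <- config@spacingMm
  step <- sp / config@refineFactor
  margin <- round(config@tissueMarginMm / step) * step
  xs <- seq(-margin, (config@gridCols - 1L) * sp + margin, by = step)
  ys <- seq(-margin, (config@gridRows - 1L) * sp + margin, by = step)
  list(xs = xs, ys = ys, step = step)
}

## does segment (p1, p2) cross segment (q1, q2)? proper or touching
.segmentsCross <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- orient(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- orient(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- orient(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- orient(p1x, p1y, p2x, p2y, q2x, q2y)
  (d1 * d2 <= 0) & (d3 * d4 <= 0) & !(d1 == 0 & d2 == 0)
}

#' Generate the ground-truth activation field
#'
#' Computes the local activation time at every tissue node as the geodesic
#' travel time from the activation source over an 8-connected lattice (edge
#' weight = distance / conduction velocity; an edge crossing a block line
#' incurs that line's delay, so wavefronts either detour around a line or
#' cross it late). Plane waves are seeded on the upstream lattice edge,
#' focal sources at the lattice node nearest the chosen origin. Electrode
#' LATs are read off the lattice at the electrode positions and repeated
#' for each beat at the configured cycle length.
#'
#' @param config a [SimulationConfig-class]
#' @return a [GroundTruth-class]
#' @examples
#' cfg <- SimulationConfig(gridRows = 4, gridCols = 4, cvMmPerMs = 1,
#'                         nBeats = 1, durationS = 1)
#' truth <- generateLatField(cfg)
#' latMatrix(truth)
#' @export
generateLatField <- function(config) {
  validObject(config)
  lat <- .tissueLattice(config)
  nx <- length(lat$xs); ny <- length(lat$ys)
  n <- nx * ny
  ## node k = (ix - 1) * ny + iy, coordinates (xs[ix], ys[iy])
  ix <- rep(seq_len(nx), each = ny)
  iy <- rep(seq_len(ny), times = nx)
  px <- lat$xs[ix]; py <- lat$ys[iy]

  ## 8-connected edges (store once per unordered pair)
  shifts <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  efrom <- integer(); eto <- integer()
  for (s in seq_len(nrow(shifts))) {
    jx <- ix + shifts[s, 1L]; jy <- iy + shifts[s, 2L]
    ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny
    efrom <- c(efrom, which(ok))
    eto <- c(eto, ((jx - 1L) * ny + jy)[ok])
  }
  dist <- sqrt((px[efrom] - px[eto])^2 + (py[efrom] - py[eto])^2)
  wt <- dist / config@cvMmPerMs
  bl <- config@blockLines
  if (NROW(bl) > 0L) {
    for (k in seq_len(nrow(bl))) {
      crosses <- .segmentsCross(px[efrom], py[efrom], px[eto], py[eto],
                                bl$x0[k], bl$y0[k], bl$x1[k], bl$y1[k])
      wt[crosses] <- wt[crosses] + bl$delay_ms[k]
    }
  }

  ## source set
  if (config@sourceType == "plane") {
    th <- config@directionDeg * pi / 180
    proj <- px * cos(th) + py * sin(th)
    src <- which(proj <= min(proj) + lat$step / 2)
  } else {
    src <- which.min((px - config@focalOriginMm[1L])^2 +
                     (py - config@focalOriginMm[2L])^2)
  }

  ## Dijkstra (multi-source); adjacency built from the symmetric edge list
  adjFrom <- c(efrom, eto)
  adjTo <- c(eto, efrom)
  adjW <- c(wt, wt)
  ord <- order(adjFrom)
  adjFrom <- adjFrom[ord]; adjTo <- adjTo[ord]; adjW <- adjW[ord]
  firstEdge <- c(match(seq_len(n), adjFrom), length(adjFrom) + 1L)
  d <- rep(Inf, n)
  d[src] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, d))
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    a <- firstEdge[u]; b <- firstEdge[u + 1L] - 1L
    if (is.na(a) || b < a) next
    vs <- adjTo[a:b]
    nd <- d[u] + adjW[a:b]
    upd <- nd < d[vs]
    d[vs[upd]] <- nd[upd]
  }
  if (any(!is.finite(d)))
    .warnf("%d unreachable tissue node(s); their LAT is absent",
           sum(!is.finite(d)))
  field <- matrix(NA_real_, ny, nx)
  field[cbind(iy, ix)] <- ifelse(is.finite(d), d, NA_real_)

  ## electrode LATs (relative to the beat fiducial)
  sp <- config@spacingMm
  elLat <- matrix(NA_real_, config@gridRows, config@gridCols)
  exIx <- round(((0:(config@gridCols - 1L)) * sp - lat$xs[1L]) / lat$step) + 1L
  exIy <- round(((0:(config@gridRows - 1L)) * sp - lat$ys[1L]) / lat$step) + 1L
  for (r in seq_len(config@gridRows))
    for (cc in seq_len(config@gridCols))
      elLat[r, cc] <- field[exIy[r], exIx[cc]]

  beatTimes <- config@firstBeatMs +
    (seq_len(config@nBeats) - 1L) * config@cycleLengthMs

  ## geometry-derived expectations
  cbExp <- .expectedCbPairs(elLat, 12)
  expType <- .expectedTypes(config, sp)

  new("GroundTruth", latMs = elLat, beatTimesMs = beatTimes,
      tissueLat = list(xs = lat$xs, ys = lat$ys, lat = field,
                       step = lat$step),
      blockLines = bl, cbExpected = cbExp, expectedType = expType,
      config = config)
}

.expectedCbPairs <- function(elLat, thr) {
  nr <- nrow(elLat); nc <- ncol(elLat)
  out <- .emptyCbEdges()
  pairs <- .rookPairs(nr, nc)
  ok <- !is.na(elLat[pairs[, 1L]]) & !is.na(elLat[pairs[, 2L]])
  dl <- abs(elLat[pairs[, 1L]] - elLat[pairs[, 2L]])
  sel <- ok & dl >= thr
  if (any(sel)) {
    rc1 <- .gridRowCol(pairs[sel, 1L], nr)
    rc2 <- .gridRowCol(pairs[sel, 2L], nr)
    out <- data.frame(row1 = rc1[, 1L], col1 = rc1[, 2L], row2 = rc2[, 1L],
                      col2 = rc2[, 2L], dlat_ms = dl[sel])
  }
  out
}

## distance from point to segment
.pointSegDist <- function(pxv, pyv, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((pxv - x0) * vx + (pyv - y0) * vy) / L2))
  sqrt((pxv - (x0 + t * vx))^2 + (pyv - (y0 + t * vy))^2)
}

.expectedTypes <- function(config, sp) {
  nr <- config@gridRows; nc <- config@gridCols
  out <- matrix("SP", nr, nc)
  bl <- config@blockLines
  if (NROW(bl) == 0L) return(out)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    pxv <- (cc - 1L) * sp; pyv <- (r - 1L) * sp
    for (k in seq_len(nrow(bl))) {
      if (bl$delay_ms[k] >= 15 &&
          .pointSegDist(pxv, pyv, bl$x0[k], bl$y0[k], bl$x1[k], bl$y1[k]) <=
            config@truncationRadiusMm) {
        out[r, cc] <- "LDP"
        break
      }
    }
  }
  out
}

## -------------------------------------------------------------- forward --

#' Synthesize unipolar electrograms from a ground-truth field
#'
#' Signed source-summation forward model. Every tissue node within the
#' truncation radius of an electrode contributes a Gaussian pulse centred
#' on its activation time, weighted by \eqn{(1 + d / spacing)^{-decay}}
#' (scaled by \code{farFieldGain} beyond \code{farFieldRadiusMm}); the
#' contribution is positive while the wavefront approaches the electrode
#' (node activates before the tissue under the electrode) and negative
#' while it recedes. The superposition yields the classic R-S morphology of
#' the unipolar electrogram, a solely-S morphology at a focal origin (no
#' approaching front), and delayed extra deflections — double potentials —
#' on electrodes adjacent to lines of conduction block. Gaussian noise of
#' sd \code{noiseSigmaMv} is added with the RNG seeded from the config; the
#' reference channel is a noise-free fiducial pulse train at the beat
#' times. Voltages are quantized to float32 so bundle round trips are
#' exact.
#'
#' @param truth a [GroundTruth-class] from [generateLatField()]
#' @param config the matching [SimulationConfig-class]
#' @param region region label for the resulting recording
#' @param siteId site label
#' @return a [SiteRecording-class]
#' @export
synthesizeEgms <- function(truth, config = truth@config, region = "RA",
                           siteId = "site1") {
  tl <- truth@tissueLat
  nx <- length(tl$xs); ny <- length(tl$ys)
  nodeX <- rep(tl$xs, each = ny)
  nodeY <- rep(tl$ys, times = nx)
  nodeLat <- as.numeric(tl$lat)   # column-major: (iy, ix) -> iy + (ix-1)*ny
  nr <- config@gridRows; nc <- config@gridCols
  sp <- config@spacingMm
  nSamp <- as.integer(round(config@durationS * 1000))
  tau <- config@kernelWidthMs / 4
  supp <- 4 * tau
  sig <- matrix(0, nr * nc, nSamp)
  tms <- 0:(nSamp - 1L)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    e <- .rowColToIdx(r, cc, nc)
    ex <- (cc - 1L) * sp; ey <- (r - 1L) * sp
    dd <- sqrt((nodeX - ex)^2 + (nodeY - ey)^2)
    sel <- which(dd <= config@truncationRadiusMm & !is.na(nodeLat))
    fe <- truth@latMs[r, cc]
    if (length(sel) == 0L || is.na(fe)) next
    w <- (1 + dd[sel] / sp)^(-config@decayExponent)
    w[dd[sel] > config@farFieldRadiusMm] <-
      w[dd[sel] > config@farFieldRadiusMm] * config@farFieldGain
    sgn <- sign(fe - nodeLat[sel])
    keep <- sgn != 0
    if (!any(keep)) next
    w <- w[keep] * sgn[keep] * config@amplitudeMv
    lats <- nodeLat[sel][keep]
    for (k in seq_along(truth@beatTimesMs)) {
      centre <- truth@beatTimesMs[k] + lats
      i0 <- max(1L, floor(min(centre) - supp) + 1L)
      i1 <- min(nSamp, ceiling(max(centre) + supp) + 1L)
      if (i1 <= i0) next
      tt <- tms[i0:i1]
      M <- outer(tt, centre, "-")
      sig[e, i0:i1] <- sig[e, i0:i1] + as.numeric(exp(-M^2 / (2 * tau^2)) %*% w)
    }
  }
  if (config@noiseSigmaMv > 0) {
    sig <- sig + .withSeed(config@seed,
      matrix(stats::rnorm(length(sig), sd = config@noiseSigmaMv),
             nrow(sig), ncol(sig)))
  }
  ## noise-free fiducial train on the reference channel
  ref <- numeric(nSamp)
  for (bt in truth@beatTimesMs) {
    i0 <- max(1L, floor(bt - 15) + 1L)
    i1 <- min(nSamp, ceiling(bt + 15) + 1L)
    ref[i0:i1] <- ref[i0:i1] + exp(-(tms[i0:i1] - bt)^2 / (2 * 3^2))
  }
  arr <- ElectrodeArray(nr, nc, sp)
  SiteRecording(arr, region, .asFloat32(sig), fsHz = 1000,
                reference = .asFloat32(ref), siteId = siteId)
}

#' Simulate one mapping site
#'
#' Convenience wrapper: [generateLatField()] followed by
#' [synthesizeEgms()].
#'
#' @inheritParams synthesizeEgms
#' @param config a [SimulationConfig-class]
#' @return list with elements \code{site} ([SiteRecording-class]) and
#'   \code{truth} ([GroundTruth-class])
#' @export
simulateSite <- function(config, region = "RA", siteId = "site1") {
  truth <- generateLatField(config)
  list(site = synthesizeEgms(truth, config, region = region,
                             siteId = siteId),
       truth = truth)
}

#' Simulate a whole patient at a given block-line density
#'
#' Generates one or more sites per atrial region from a template
#' configuration, placing a Poisson-distributed number of random block
#' lines (expectation \code{blockDensity} per site) with crossing delays
#' drawn uniformly from 12-30 ms. All randomness (line count, geometry,
#' delays, per-site noise seeds) flows from \code{seed}, so the same seed
#' reproduces the same dataset exactly.
#'
#' @param blockDensity expected number of block lines per site (>= 0)
#' @param nSitesPerRegion sites per region
#' @param template a [SimulationConfig-class] used for every site
#' @param seed integer seed
#' @param patientIdLabel patient label
#' @return list with elements \code{dataset} ([PatientDataset-class]) and
#'   \code{truths} (named list of [GroundTruth-class], one per site)
#' @export
generatePatient <- function(blockDensity = 1, nSitesPerRegion = 1,
                            template = SimulationConfig(), seed = 1L,
                            patientIdLabel = sprintf("sim%04d", seed)) {
  stopifnot(blockDensity >= 0)
  .withSeed(seed, {
    sitesList <- list()
    truths <- list()
    sp <- template@spacingMm
    wX <- (template@gridCols - 1L) * sp
    wY <- (template@gridRows - 1L) * sp
    step <- sp / template@refineFactor
    for (reg in REGIONS) {
      for (s in seq_len(nSitesPerRegion)) {
        nLines <- stats::rpois(1L, blockDensity)
        bl <- emptyBlockLines()
        margin <- template@tissueMarginMm + 2
        for (l in seq_len(nLines)) {
          vertical <- stats::runif(1) < 0.5
          ## line length as a fraction of the full tissue extent: >= 1 is a
          ## complete line of block, < 1 leaves a pivot point at one end
          frac <- stats::runif(1, 0.6, 1.2)
          delay <- stats::runif(1, 12, 30)
          fromTop <- stats::runif(1) < 0.5
          if (vertical) {
            ## snap to half-step offsets so lattice nodes never sit on a line
            x <- (round(stats::runif(1, 0.25, 0.75) * wX / step) + 0.5) * step
            ext <- wY + 2 * margin
            len <- min(frac, 1) * ext
            y0 <- if (fromTop) -margin else wY + margin - len
            bl <- rbind(bl, blockLine(x, y0, x, y0 + len, delay))
          } else {
            y <- (round(stats::runif(1, 0.25, 0.75) * wY / step) + 0.5) * step
            ext <- wX + 2 * margin
            len <- min(frac, 1) * ext
            x0 <- if (fromTop) -margin else wX + margin - len
            bl <- rbind(bl, blockLine(x0, y, x0 + len, y, delay))
          }
        }
        cfg <- template
        cfg@blockLines <- bl
        cfg@seed <- sample.int(2147483646L, 1L)
        id <- sprintf("%s_s%d", reg, s)
        sim <- simulateSite(cfg, region = reg, siteId = id)
        sitesList[[id]] <- sim$site
        truths[[id]] <- sim$truth
      }
    }
    list(dataset = PatientDataset(patientIdLabel, unname(sitesList)),
         truths = truths)
  })
}

#' Write simulator ground truth as a sidecar document
#'
#' Structured YAML per site: beat times, the electrode LAT grid, block
#' lines and geometry-derived expectations.
#'
#' @param truth a [GroundTruth-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeGroundTruth <- function(truth, path) {
  doc <- list(
    beat_times_ms = truth@beatTimesMs,
    lat_ms = apply(truth@latMs, 1L, as.numeric, simplify = FALSE),
    block_lines = if (nrow(truth@blockLines)) truth@blockLines else NULL,
    cb_expected_pairs = nrow(truth@cbExpected),
    expected_type = apply(truth@expectedType, 1L, as.character,
                          simplify = FALSE))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}
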