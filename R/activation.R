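#' @include AllClasses.R
NULL

#' Build a per-beat activation map
#'
#' Places per-electrode LATs onto the grid of a recording site. Electrodes
#' flagged bad in \code{channelQuality} get no LAT. Exclusion of
#' simultaneous-activation areas and conduction-block detection are applied
#' afterwards by [excludeSimultaneousAreas()] and
#' [detectConductionBlock()].
#'
#' @param site a [SiteRecording-class]
#' @param lats numeric nRows x nCols matrix of LATs (ms; \code{NA} where no
#'   potential)
#' @param beat beat index
#' @return an [ActivationMap-class]
#' @export
buildActivationMap <- function(site, lats, beat = 1L) {
  arr <- electrodeGrid(site)
  if (!identical(dim(lats), c(nRows(arr), nCols(arr))))
    .stopf("LAT grid is %d x %d but the array is %d x %d",
           nrow(lats), ncol(lats), nRows(arr), nCols(arr))
  bad <- matrix(!channelQuality(site), nrow = nRows(arr),
                ncol = nCols(arr), byrow = TRUE)
  lats[bad] <- NA_real_
  if (all(is.na(lats)))
    .warnf("activation map of beat %d is empty (no usable LAT)", beat)
  new("ActivationMap", latMs = lats,
      excluded = matrix(FALSE, nrow(lats), ncol(lats)),
      cbEdges = .emptyCbEdges(), beat = as.integer(beat),
      evaluablePairs = NA_integer_, cbPercentage = NA_real_)
}

.emptyCbEdges <- function() {
  data.frame(row1 = integer(), col1 = integer(), row2 = integer(),
             col2 = integer(), dlat_ms = numeric())
}

## rook-adjacent pairs of a nr x nc grid with both LATs present;
## returns matrix of linear indices (i, j)
.rookPairs <- function(nr, nc) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  horiz <- cbind(as.vector(idx[, -nc, drop = FALSE]),
                 as.vector(idx[, -1, drop = FALSE]))
  vert <- cbind(as.vector(idx[-nr, , drop = FALSE]),
                as.vector(idx[-1, , drop = FALSE]))
  rbind(horiz, vert)
}

#' Exclude simultaneous-activation areas
#'
#' Spatially extended plateaus of near-identical LATs are the signature of
#' far-field potentials rather than local activation; they are excluded so
#' that far-field deflections do not enter conduction-block analysis.
#' A connected component (rook adjacency) of at least
#' \code{simultaneityMinArea} electrodes whose neighbouring LATs differ by
#' at most \code{simultaneityToleranceMs} is marked excluded.
#'
#' @param map an [ActivationMap-class]
#' @param params an [AnalysisParams-class]
#' @return the map with its \code{excluded} mask updated
#' @export
excludeSimultaneousAreas <- function(map, params = AnalysisParams()) {
  lat <- map@latMs
  nr <- nrow(lat); nc <- ncol(lat)
  pairs <- .rookPairs(nr, nc)
  ok <- !is.na(lat[pairs[, 1L]]) & !is.na(lat[pairs[, 2L]]) &
    abs(lat[pairs[, 1L]] - lat[pairs[, 2L]]) <= params@simultaneityToleranceMs
  pairs <- pairs[ok, , drop = FALSE]
  excl <- matrix(FALSE, nr, nc)
  if (nrow(pairs)) {
    ## union-find over simultaneity edges
    parent <- seq_len(nr * nc)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[a] <- b
    }
    member <- unique(as.vector(pairs))
    roots <- vapply(member, find, integer(1))
    sizes <- table(roots)
    big <- as.integer(names(sizes)[sizes >= params@simultaneityMinArea])
    excl[member[roots %in% big]] <- TRUE
  }
  map@excluded <- excl
  map
}

#' Detect conduction block on an activation map
#'
#' Every rook-adjacent electrode pair with both LATs present and neither
#' electrode excluded is evaluable; the pair is a conduction-block edge when
#' the absolute LAT difference is at or above \code{cbThresholdMs} (12 ms by
#' default, inclusive). The CB percentage is 100 times the number of block
#' edges over the number of evaluable pairs.
#'
#' @param map an [ActivationMap-class] (after exclusion)
#' @param params an [AnalysisParams-class]
#' @return the map with \code{cbEdges}, \code{evaluablePairs} and
#'   \code{cbPercentage} filled in; the percentage is \code{NA} (with a
#'   warning) when no pair is evaluable
#' @export
detectConductionBlock <- function(map, params = AnalysisParams()) {
  lat <- map@latMs
  nr <- nrow(lat); nc <- ncol(lat)
  pairs <- .rookPairs(nr, nc)
  usable <- !is.na(lat[pairs[, 1L]]) & !is.na(lat[pairs[, 2L]]) &
    !map@excluded[pairs[, 1L]] & !map@excluded[pairs[, 2L]]
  pairs <- pairs[usable, , drop = FALSE]
  nEval <- nrow(pairs)
  if (nEval == 0L) {
    .warnf("no evaluable adjacent pair on beat %d; CB percentage undefined",
           map@beat)
    map@cbEdges <- .emptyCbEdges()
    map@evaluablePairs <- 0L
    map@cbPercentage <- NA_real_
    return(map)
  }
  dlat <- abs(lat[pairs[, 1L]] - lat[pairs[, 2L]])
  blocked <- dlat >= params@cbThresholdMs
  bp <- pairs[blocked, , drop = FALSE]
  rc1 <- .gridRowCol(bp[, 1L], nr)
  rc2 <- .gridRowCol(bp[, 2L], nr)
  map@cbEdges <- data.frame(row1 = rc1[, 1L], col1 = rc1[, 2L],
                            row2 = rc2[, 1L], col2 = rc2[, 2L],
                            dlat_ms = dlat[blocked])
  map@evaluablePairs <- nEval
  map@cbPercentage <- 100 * sum(blocked) / nEval
  map
}

## column-major linear index -> (row, col) for matrices
.gridRowCol <- function(idx, nr) {
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}
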