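#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the S4 containers in this package. Slot
#' access from user code should always go through these.
#'
#' @param x an object of the documented class
#' @return the slot value (see the class documentation)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname accessors
#' @export
setGeneric("electrodeIds", function(x) standardGeneric("electrodeIds"))

#' @rdname accessors
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("referenceTrace", function(x) standardGeneric("referenceTrace"))

#' @rdname accessors
#' @export
setGeneric("channelQuality", function(x) standardGeneric("channelQuality"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname accessors
#' @export
setGeneric("electrodeGrid", function(x) standardGeneric("electrodeGrid"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @rdname accessors
#' @export
setGeneric("latMatrix", function(x) standardGeneric("latMatrix"))

#' @rdname accessors
#' @export
setGeneric("excludedMask", function(x) standardGeneric("excludedMask"))

#' @rdname accessors
#' @export
setGeneric("cbEdges", function(x) standardGeneric("cbEdges"))

#' @rdname accessors
#' @export
setGeneric("cbPercentage", function(x) standardGeneric("cbPercentage"))

#' @rdname accessors
#' @export
setGeneric("regionFingerprints", function(x) standardGeneric("regionFingerprints"))

#' @rdname accessors
#' @export
setGeneric("overallFingerprint", function(x) standardGeneric("overallFingerprint"))

#' @rdname accessors
#' @export
setGeneric("ldpFpBurden", function(x) standardGeneric("ldpFpBurden"))

#' @rdname accessors
#' @export
setGeneric("sigmaMv", function(x) standardGeneric("sigmaMv"))
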