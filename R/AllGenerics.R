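#' Accessors for dociR objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `channel()` the emission wavelength, `timeGrid()` the sample times,
#' `stackFrames()` the raw count array, `dociValues()` the DOCI value matrix,
#' `validMask()` the low-signal mask, `profilePositions()` / `profileValues()`
#' the nerve-axis profile, `statsTable()` / `contrastScores()` /
#' `bestChannel()` the significance-sweep results, and `pniLabel()` /
#' `pniScore()` / `transitionIndex()` the caller output.
#'
#' @param x a dociR S4 object
#' @return the corresponding slot content; `bestChannel()` returns the
#'   wavelength (nm) with the highest contrast score (ties broken by channel
#'   order)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))
#' @rdname accessors
#' @export
setGeneric("stackFrames", function(x) standardGeneric("stackFrames"))
#' @rdname accessors
#' @export
setGeneric("dociValues", function(x) standardGeneric("dociValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
#' @rdname accessors
#' @export
setGeneric("contrastScores", function(x) standardGeneric("contrastScores"))
#' @rdname accessors
#' @export
setGeneric("bestChannel", function(x) standardGeneric("bestChannel"))
#' @rdname accessors
#' @export
setGeneric("pniLabel", function(x) standardGeneric("pniLabel"))
#' @rdname accessors
#' @export
setGeneric("pniScore", function(x) standardGeneric("pniScore"))
#' @rdname accessors
#' @export
setGeneric("transitionIndex", function(x) standardGeneric("transitionIndex"))

#' @rdname accessors
setMethod("channel", "TimeResolvedStack", function(x) x@channel)
#' @rdname accessors
setMethod("channel", "DOCIImage", function(x) x@channel)
#' @rdname accessors
setMethod("channel", "NerveProfile", function(x) x@channel)
#' @rdname accessors
setMethod("timeGrid", "TimeResolvedStack", function(x) x@timeGrid)
#' @rdname accessors
setMethod("stackFrames", "TimeResolvedStack", function(x) x@frames)
#' @rdname accessors
setMethod("dociValues", "DOCIImage", function(x) x@values)
#' @rdname accessors
setMethod("validMask", "DOCIImage", function(x) x@validMask)
#' @rdname accessors
setMethod("profilePositions", "NerveProfile", function(x) x@positions)
#' @rdname accessors
setMethod("profileValues", "NerveProfile", function(x) x@values)
#' @rdname accessors
setMethod("statsTable", "ROIStatsTable", function(x) x@table)
#' @rdname accessors
setMethod("contrastScores", "ROIStatsTable", function(x) x@contrast)
#' @rdname accessors
setMethod("bestChannel", "ROIStatsTable", function(x) {
  sc <- x@contrast
  sc$channel_nm[which.max(sc$score)]
})
#' @rdname accessors
setMethod("pniLabel", "PNICallResult", function(x) x@label)
#' @rdname accessors
setMethod("pniScore", "PNICallResult", function(x) x@score)
#' @rdname accessors
setMethod("transitionIndex", "PNICallResult", function(x) x@transitionIndex)
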