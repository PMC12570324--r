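#' Accessor generics
#'
#' Small accessor layer over the S4 containers; user code should use these
#' rather than reaching into slots.
#'
#' @param object an htsqc S4 object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname accessors
#' @export
setGeneric("wellData", function(object) standardGeneric("wellData"))

#' @rdname accessors
#' @export
setGeneric("plateDim", function(object) standardGeneric("plateDim"))

#' @rdname accessors
#' @export
setGeneric("nrfe", function(object) standardGeneric("nrfe"))

#' @rdname accessors
#' @export
setGeneric("qcTier", function(object) standardGeneric("qcTier"))

#' @rdname accessors
#' @export
setGeneric("controlMetrics", function(object, ...) standardGeneric("controlMetrics"))

#' @rdname accessors
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))

#' @rdname accessors
#' @export
setGeneric("fitResiduals", function(object) standardGeneric("fitResiduals"))

#' @rdname accessors
#' @export
setGeneric("fitCoefficients", function(object) standardGeneric("fitCoefficients"))

#' @rdname accessors
#' @export
setMethod("plateId", "PlateData", function(object) object@plateId)

#' @rdname accessors
#' @export
setMethod("plateId", "PlateQCResult", function(object) object@plateId)

#' @rdname accessors
#' @export
setMethod("wellData", "PlateData", function(object) object@wells)

#' @rdname accessors
#' @export
setMethod("plateDim", "PlateData", function(object) c(object@nRows, object@nCols))

#' @rdname accessors
#' @export
setMethod("nrfe", "PlateQCResult", function(object) object@nrfe)

#' @rdname accessors
#' @export
setMethod("qcTier", "PlateQCResult", function(object) object@tier)

#' @rdname accessors
#' @export
setMethod("fitStatus", "LL4Fit", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("fitResiduals", "LL4Fit", function(object) object@residuals)

#' @rdname accessors
#' @export
setMethod("fitCoefficients", "LL4Fit", function(object) {
  c(a = object@a, b = object@b, c = object@c, d = object@d)
})
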