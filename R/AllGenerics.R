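#' @name plateKinetics-accessors
#' @title Accessors for PlateTimeSeries objects
#'
#' @description
#' \code{plateTime} returns the shared time vector (hours); \code{plateOD}
#' the OD matrix (rows = time points, named columns = wells);
#' \code{wellIds} the ordered well labels; \code{nWells} the number of wells;
#' \code{wellAnnotations} the annotation \code{data.frame} (zero rows when
#' no layout has been attached), and \code{wellAnnotations<-} replaces it
#' after validation.
#'
#' @param x A [PlateTimeSeries-class] object.
#' @param value Replacement annotation \code{data.frame}.
#' @return The corresponding component.
NULL

#' @rdname plateKinetics-accessors
#' @export
setGeneric("plateTime", function(x) standardGeneric("plateTime"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("plateOD", function(x) standardGeneric("plateOD"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("wellIds", function(x) standardGeneric("wellIds"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("nWells", function(x) standardGeneric("nWells"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("wellAnnotations", function(x) standardGeneric("wellAnnotations"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("wellAnnotations<-", function(x, value) standardGeneric("wellAnnotations<-"))

#' Evaluate a smoothed curve or its derivatives
#'
#' @param curve A [SmoothedCurve-class].
#' @param t Numeric evaluation times within the observation interval.
#' @param deriv Derivative order: 0, 1 or 2.
#' @return Numeric vector of values.
#' @export
setGeneric("evalCurve", function(curve, t, deriv = 0L) standardGeneric("evalCurve"))

#' Integrated squared second derivative of a fit
#'
#' @param curve A [SmoothedCurve-class].
#' @param nGrid Grid resolution.
#' @return Scalar roughness.
#' @export
setGeneric("curveRoughness", function(curve, nGrid = 4001L) standardGeneric("curveRoughness"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("smoothingFactor", function(x) standardGeneric("smoothingFactor"))

#' @rdname plateKinetics-accessors
#' @export
setGeneric("curveScale", function(x) standardGeneric("curveScale"))
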