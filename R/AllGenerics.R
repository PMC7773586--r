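#' @include AllGenerics.R
NULL

#' Evaluate a template curve
#'
#' @param object a \linkS4class{TemplateCurve}.
#' @param t numeric vector of times (min, relative to spindle breakage).
#' @return numeric vector of intensities (a.u.).
#' @export
setGeneric("templateValue", function(object, t) standardGeneric("templateValue"))

#' @rdname accessors
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("moduleLabel", function(object) standardGeneric("moduleLabel"))

#' @rdname accessors
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))

#' @rdname accessors
#' @export
setGeneric("arrivalTime", function(object) standardGeneric("arrivalTime"))

#' @rdname accessors
#' @export
setGeneric("departureTime", function(object) standardGeneric("departureTime"))

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("diameter", function(object) standardGeneric("diameter"))

#' @rdname accessors
#' @export
setGeneric("meanCurve", function(object) standardGeneric("meanCurve"))

#' @rdname accessors
#' @export
setGeneric("sdCurve", function(object) standardGeneric("sdCurve"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(object) standardGeneric("conditionLabel"))

#' Apply a condition effect to a template or parameter object
#'
#' @param object a \linkS4class{TemplateCurve} or
#'   \linkS4class{ConstrictionParams}.
#' @param effect a \linkS4class{ConditionEffect}.
#' @return an object of the same class as \code{object} with the effect
#'   applied.
#' @export
setGeneric("applyConditionEffect",
           function(object, effect, ...) standardGeneric("applyConditionEffect"))
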