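#' Accessor generics
#'
#' Small accessor layer over the S4 containers: spectral order, nodes,
#' quadrature weights and differentiation matrix of a basis; center-point
#' series, times and control schedules of trajectories and solutions.
#'
#' @param object an object of the matching class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("basisOrder", function(object) standardGeneric("basisOrder"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("quadWeights", function(object) standardGeneric("quadWeights"))

#' @rdname accessors
#' @export
setGeneric("diffMatrix", function(object) standardGeneric("diffMatrix"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("centerSeries", function(object) standardGeneric("centerSeries"))

#' @rdname accessors
#' @export
setGeneric("controlSchedules", function(object) standardGeneric("controlSchedules"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("durationSummary", function(object) standardGeneric("durationSummary"))

#' @rdname accessors
#' @export
setGeneric("uniformityDefect", function(object) standardGeneric("uniformityDefect"))

setMethod("basisOrder", "GLLBasis", function(object) object@order)
setMethod("nodes", "GLLBasis", function(object) object@nodes)
setMethod("quadWeights", "GLLBasis", function(object) object@weights)
setMethod("diffMatrix", "GLLBasis", function(object) object@diff)

setMethod("timePoints", "TimeGrid", function(object) {
  object@t0 + (object@tEnd - object@t0) * (0:object@nSteps) / object@nSteps
})
setMethod("timePoints", "Trajectory", function(object) object@times)
setMethod("timePoints", "RiccatiPath", function(object) object@times)
setMethod("timePoints", "ControlSolution", function(object) object@trajectory@times)

setMethod("centerSeries", "Trajectory", function(object) object@center)
setMethod("centerSeries", "ControlSolution", function(object) object@trajectory@center)

setMethod("controlSchedules", "Trajectory", function(object) {
  list(etaT = object@etaT, etaG = object@etaG)
})
setMethod("controlSchedules", "ControlSolution", function(object) {
  controlSchedules(object@trajectory)
})

setMethod("objectiveValue", "ControlSolution", function(object) object@objective)
setMethod("durationSummary", "ControlSolution", function(object) object@durations)

setMethod("uniformityDefect", "Trajectory", function(object) object@uniformityDefect)
setMethod("uniformityDefect", "ControlSolution", function(object) {
  object@trajectory@uniformityDefect
})
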