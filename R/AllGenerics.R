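#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("rTimes", function(x) standardGeneric("rTimes"))

#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
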