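#' Accessors for the core signal classes
#'
#' Slot access for [ECGRecord-class], [BeatSeries-class] and
#' [SessionProtocol-class] objects. `rrIntervals()` returns the successive
#' R-R differences in ms (length one less than the number of beats);
#' `sessionDuration()` the end time (s) of the last protocol event.
#'
#' @param x an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("samples", "ECGRecord", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "ECGRecord", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("startTime", "ECGRecord", function(x) x@t0)

#' @rdname accessors
#' @export
setMethod("rTimes", "BeatSeries", function(x) x@rTimes)

#' @rdname accessors
#' @export
setMethod("rrIntervals", "BeatSeries", function(x) {
  if (length(x@rTimes) < 2L) return(numeric(0))
  diff(x@rTimes) * 1000
})

#' @rdname accessors
#' @export
setMethod("annotations", "BeatSeries", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("events", "SessionProtocol", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("sessionDuration", "SessionProtocol", function(x) {
  ev <- x@events
  ev$onset[nrow(ev)] + ev$duration[nrow(ev)]
})

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord '%s': %d samples at %g Hz (%.1f s from t0=%g s)\n",
              object@label, length(object@samples), object@fs,
              length(object@samples) / object@fs, object@t0))
})

setMethod("show", "BeatSeries", function(object) {
  n <- length(object@rTimes)
  tab <- table(factor(object@annotations, levels = BEAT_ANNOTATIONS))
  cat(sprintf("BeatSeries: %d beats", n))
  if (n >= 2L)
    cat(sprintf(", span %.1f s, mean RR %.0f ms",
                diff(range(object@rTimes)), mean(rrIntervals(object))))
  cat(sprintf("\n  annotations: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
})

setMethod("show", "SessionProtocol", function(object) {
  ev <- object@events
  ns <- sum(ev$label == "stimulus")
  cat(sprintf(
    "SessionProtocol: %d events (%d stimuli), %g s total\n  conditions: %s\n",
    nrow(ev), ns, sessionDuration(object),
    paste(ev$condition[ev$label == "stimulus"], collapse = " ")))
})

setMethod("show", "HeartPeriodModel", function(object) {
  cat(sprintf(
    "HeartPeriodModel: m0=%g ms, LF %g ms @ %g Hz, HF %g ms @ %g Hz, sigma=%g ms\n",
    object@m0, object@aLF, object@fLF, object@aHF, object@fHF, object@sigma))
  if (length(object@delta))
    cat("  delta:", paste(sprintf("%s=%+g ms", names(object@delta),
                                  object@delta), collapse = ", "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %s (seed %d, %s)\n",
              paste(sprintf("%s=%d", names(object@nPerGroup),
                            object@nPerGroup), collapse = " "),
              object@seed,
              if (object@withECG) sprintf("ECG at %g Hz", object@fs)
              else "beat-level"))
})
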