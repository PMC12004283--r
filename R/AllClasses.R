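#' @import methods
NULL

PROTOCOL_LABELS <- c("baseline", "stimulus", "rest")
STIM_CONDITIONS <- c("acquaintance", "stranger")
GROUPS <- c("HC", "MCS", "UWS")
BEAT_ANNOTATIONS <- c("normal", "ectopic", "interpolated")

#' Twelve ultra-short-term HRV measure names
#'
#' Canonical names, in reporting order, of the twelve heart rate variability
#' measures computed on each 55-s window: ten time-domain measures and the
#' high-frequency spectral pair. These names key every downstream table.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' hrvFeatureNames()
hrvFeatureNames <- function() {
  c("MeanNN", "MedianNN", "MadNN", "SDNN", "RMSSD", "SDSD",
    "Prc80NN", "Prc20NN", "pNN20", "pNN50", "HF", "HFn")
}

#' SessionProtocol: timeline of a stimulation session
#'
#' Ordered, contiguous timeline of baseline/stimulus/rest events. A default
#' session is a 60-s resting baseline followed by twelve 55-s affective
#' videos (six featuring an acquaintance, six a stranger, in seeded random
#' order), each video followed by a 55-s rest.
#'
#' @slot events data.frame with columns \code{label} (baseline/stimulus/rest),
#'   \code{condition} (acquaintance/stranger/none), \code{onset} (s),
#'   \code{duration} (s). Events are contiguous and non-overlapping.
#' @export
setClass("SessionProtocol", slots = c(events = "data.frame"))

setValidity("SessionProtocol", function(object) {
  ev <- object@events
  req <- c("label", "condition", "onset", "duration")
  if (!all(req %in% names(ev)))
    return(sprintf("events must have columns %s", paste(req, collapse = ", ")))
  if (nrow(ev) == 0L) return("protocol has no events")
  if (!all(ev$label %in% PROTOCOL_LABELS))
    return("event labels must be baseline/stimulus/rest")
  if (!all(ev$condition %in% c(STIM_CONDITIONS, "none")))
    return("conditions must be acquaintance/stranger/none")
  if (any((ev$condition != "none") != (ev$label == "stimulus")))
    return("condition must be none iff the event is not a stimulus")
  if (is.unsorted(ev$onset, strictly = TRUE))
    return("onsets must be strictly increasing")
  if (any(ev$duration <= 0)) return("durations must be positive")
  gaps <- ev$onset[-1L] - (ev$onset[-nrow(ev)] + ev$duration[-nrow(ev)])
  if (any(abs(gaps) > 1e-9)) return("events must be contiguous")
  ib <- which(ev$label == "baseline")
  if (length(ib) != 1L || ev$onset[ib] != 0 || ev$duration[ib] != 60)
    return("exactly one 60-s baseline at onset 0 is required")
  is_stim <- which(ev$label == "stimulus")
  if (length(is_stim)) {
    if (any(ev$duration[is_stim] != 55))
      return("stimulus events must last 55 s")
    nxt <- is_stim + 1L
    if (any(nxt > nrow(ev)) || any(ev$label[nxt] != "rest") ||
        any(ev$duration[nxt] != 55))
      return("every stimulus must be immediately followed by a 55-s rest")
  }
  TRUE
})

#' ECGRecord: sampled single-lead voltage trace
#'
#' @slot samples numeric vector of voltages (mV).
#' @slot fs sampling rate (Hz).
#' @slot t0 time of the first sample (s).
#' @slot label channel name.
#' @export
setClass("ECGRecord",
  slots = c(samples = "numeric", fs = "numeric", t0 = "numeric",
            label = "character"),
  prototype = prototype(t0 = 0, label = "ECG"))

setValidity("ECGRecord", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    return("samples must be finite")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("t0 must be a single finite number")
  TRUE
})

#' BeatSeries: R-peak times with per-beat annotations
#'
#' Strictly increasing R-peak times (s) with one annotation per beat:
#' \code{normal}, \code{ectopic} (ground-truth label set by the synthetic
#' injector), or \code{interpolated} (re-timed by ectopic correction).
#' Successive R-R intervals in ms are derived via [rrIntervals()].
#'
#' @slot rTimes strictly increasing beat times (s).
#' @slot annotations character vector, one flag per beat.
#' @export
setClass("BeatSeries",
  slots = c(rTimes = "numeric", annotations = "character"))

setValidity("BeatSeries", function(object) {
  if (length(object@rTimes) && is.unsorted(object@rTimes, strictly = TRUE))
    return("rTimes must be strictly increasing")
  if (!all(is.finite(object@rTimes))) return("rTimes must be finite")
  if (length(object@annotations) != length(object@rTimes))
    return("one annotation per beat is required")
  if (!all(object@annotations %in% BEAT_ANNOTATIONS))
    return("annotations must be normal/ectopic/interpolated")
  TRUE
})

#' HeartPeriodModel: sinusoidally modulated heart period
#'
#' Instantaneous heart period (ms) used by the beat generator:
#' \deqn{m(t) = m_0 + A_{LF}\sin(2\pi f_{LF} t) + A_{HF}\sin(2\pi f_{HF} t)
#'   + \delta(c(t)) + \epsilon,}
#' where \eqn{c(t)} is the stimulus condition active at \eqn{t} (delta is 0
#' outside stimulus windows) and \eqn{\epsilon \sim N(0, \sigma^2)} is
#' per-beat white noise. LF/HF frequencies must sit in the conventional
#' autonomic bands (LF 0.04-0.15 Hz, HF 0.15-0.4 Hz).
#'
#' @slot m0 baseline heart period (ms), positive.
#' @slot aLF,aHF modulation amplitudes (ms), non-negative.
#' @slot fLF,fHF modulation frequencies (Hz).
#' @slot sigma white-noise SD of the heart period (ms), non-negative.
#' @slot delta named numeric: additive heart-period shift (ms) applied while
#'   a stimulus of that condition is on screen.
#' @export
setClass("HeartPeriodModel",
  slots = c(m0 = "numeric", aLF = "numeric", aHF = "numeric",
            fLF = "numeric", fHF = "numeric", sigma = "numeric",
            delta = "numeric"),
  prototype = prototype(m0 = 850, aLF = 20, aHF = 25, fLF = 0.1,
                        fHF = 0.25, sigma = 10,
                        delta = c(acquaintance = 25, stranger = 0)))

setValidity("HeartPeriodModel", function(object) {
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@m0) || object@m0 <= 0) return("m0 must be positive")
  if (!one(object@aLF) || object@aLF < 0 || !one(object@aHF) || object@aHF < 0)
    return("amplitudes must be non-negative")
  if (!one(object@sigma) || object@sigma < 0)
    return("sigma must be non-negative")
  if (!one(object@fLF) || object@fLF < 0.04 || object@fLF >= 0.15)
    return("fLF must lie in [0.04, 0.15)")
  if (!one(object@fHF) || object@fHF < 0.15 || object@fHF > 0.4)
    return("fHF must lie in [0.15, 0.4]")
  if (length(object@delta) &&
      (is.null(names(object@delta)) ||
       !all(names(object@delta) %in% STIM_CONDITIONS)))
    return("delta must be named by stimulus condition")
  TRUE
})

#' CohortSpec: recipe for a seeded synthetic cohort
#'
#' @slot nPerGroup named integer, subjects per group (HC/MCS/UWS).
#' @slot groupEffectScale named numeric, multiplier applied to the model's
#'   condition deltas per group (0 silences the condition response).
#' @slot model [HeartPeriodModel-class] shared by all subjects.
#' @slot seed master seed; per-subject seeds derive from it deterministically.
#' @slot withECG synthesize waveforms (TRUE) or stop at beat series (FALSE).
#' @slot fs sampling rate for synthesized ECG (Hz).
#' @slot noise list(wanderAmp, wanderFreq, mainsAmp, whiteSd) for ECG synthesis.
#' @slot ectopicFraction proportion of beats displaced as ectopics.
#' @export
setClass("CohortSpec",
  slots = c(nPerGroup = "integer", groupEffectScale = "numeric",
            model = "HeartPeriodModel", seed = "integer",
            withECG = "logical", fs = "numeric", noise = "list",
            ectopicFraction = "numeric"),
  prototype = prototype(
    nPerGroup = c(HC = 17L, MCS = 5L, UWS = 6L),
    groupEffectScale = c(HC = 1, MCS = 0, UWS = 0),
    seed = 1L, withECG = FALSE, fs = 256,
    noise = list(wanderAmp = 0.2, wanderFreq = 0.25, mainsAmp = 0.05,
                 whiteSd = 0.05),
    ectopicFraction = 0))

setValidity("CohortSpec", function(object) {
  if (!all(GROUPS %in% names(object@nPerGroup)))
    return("nPerGroup must name HC, MCS and UWS")
  if (any(object@nPerGroup < 0L)) return("group counts must be >= 0")
  if (!all(GROUPS %in% names(object@groupEffectScale)))
    return("groupEffectScale must name HC, MCS and UWS")
  if (any(object@groupEffectScale < 0))
    return("effect multipliers must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  if (object@fs < 128) return("fs must be at least 128 Hz")
  if (object@ectopicFraction < 0 || object@ectopicFraction >= 1)
    return("ectopicFraction must lie in [0, 1)")
  TRUE
})
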