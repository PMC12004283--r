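#' Generate a randomized affective-stimulation protocol
#'
#' Builds the session timeline used throughout the pipeline: a 60-s resting
#' baseline at time 0, followed by `nStimuli` 55-s video presentations
#' (half acquaintance, half stranger, shuffled by `seed`), each immediately
#' followed by a 55-s rest. With `samBreak = TRUE` an additional 55-s
#' rest-labelled gap is inserted between each video and its rest, emulating
#' the self-report interlude of the healthy-subject session variant; its
#' content is out of scope, only its timing matters.
#'
#' @param seed integer seed controlling the condition order.
#' @param nStimuli even, positive number of video presentations (default 12).
#' @param samBreak insert the 55-s self-report gap after each video.
#' @return A [SessionProtocol-class].
#' @export
#' @examples
#' p <- generateProtocol(seed = 1)
#' events(p)[1:4, ]
generateProtocol <- function(seed, nStimuli = 12L, samBreak = FALSE) {
  nStimuli <- as.integer(nStimuli)
  if (length(nStimuli) != 1L || is.na(nStimuli) || nStimuli < 2L ||
      nStimuli %% 2L != 0L)
    stopConfig("nStimuli must be a positive even integer (got %s)",
               deparse(nStimuli))
  conds <- rep(STIM_CONDITIONS, each = nStimuli %/% 2L)
  conds <- withSeed(seed, sample(conds))

  label <- "baseline"; condition <- "none"; duration <- 60
  per <- if (samBreak) c(55, 55, 55) else c(55, 55)
  for (i in seq_len(nStimuli)) {
    label <- c(label, "stimulus", if (samBreak) "rest", "rest")
    condition <- c(condition, conds[i], if (samBreak) "none", "none")
    duration <- c(duration, per)
  }
  onset <- cumsum(c(0, duration[-length(duration)]))
  new("SessionProtocol",
      events = data.frame(label = label, condition = condition,
                          onset = onset, duration = duration,
                          stringsAsFactors = FALSE))
}
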