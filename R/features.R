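#' Extract the twelve HRV measures for one protocol window
#'
#' Selects the intervals whose *terminating* beat lies in the half-open
#' window `[start, end)` -- so every interval belongs to exactly one
#' contiguous window -- and combines [timeDomainFeatures()] and
#' [frequencyDomainFeatures()] into a single feature vector. A window with
#' fewer than 4 qualifying intervals is marked invalid and propagates as
#' missing; it is never silently zero-filled. The spectral pair is set to
#' `NA` (with a reason) when its own preconditions (10 intervals, 30 s of
#' span) are unmet while the time-domain part is still computable.
#'
#' @param beats a [BeatSeries-class].
#' @param window numeric `c(start, end)` in seconds.
#' @param windowId optional identifier carried through to tables.
#' @param madConstant passed to [timeDomainFeatures()].
#' @return List with `valid`, `features` (named numeric, the twelve measures),
#'   `nIntervals`, `windowId`, `flags` (character).
#' @export
extractFeatures <- function(beats, window, windowId = NA_integer_,
                            madConstant = 1.4826) {
  validObject(beats)
  if (length(window) != 2L || window[2L] <= window[1L])
    stopConfig("window must be c(start, end) with end > start")
  t <- beats@rTimes
  empty <- rep(NA_real_, 12L)
  names(empty) <- hrvFeatureNames()
  if (length(t) < 2L)
    return(list(valid = FALSE, features = empty, nIntervals = 0L,
                windowId = windowId, flags = "no-beats"))
  term <- t[-1L]
  sel <- which(term >= window[1L] & term < window[2L])
  if (length(sel) < 4L)
    return(list(valid = FALSE, features = empty, nIntervals = length(sel),
                windowId = windowId, flags = "too-few-intervals"))
  rr <- diff(t)[sel] * 1000  # beat times are seconds; features work in ms
  bt <- t[c(sel[1L], sel + 1L)]
  feats <- timeDomainFeatures(rr, madConstant = madConstant)
  flags <- character(0)
  span <- bt[length(bt)] - bt[1L]
  if (length(rr) >= 10L && span >= 30) {
    fd <- frequencyDomainFeatures(rr, bt)
    feats$HF <- fd$HF
    feats$HFn <- fd$HFn
    if (fd$lowReliability) flags <- c(flags, "hf-low-reliability")
    if (fd$degenerate) flags <- c(flags, "hf-degenerate")
  } else {
    feats$HF <- NA_real_
    feats$HFn <- NA_real_
    flags <- c(flags, "hf-unavailable")
  }
  fv <- unlist(feats)[hrvFeatureNames()]
  list(valid = TRUE, features = fv, nIntervals = length(sel),
       windowId = windowId, flags = flags)
}
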