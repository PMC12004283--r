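#' Detect and correct ectopic beats by local-median screening
#'
#' An automated, reproducible surrogate for visual ectopy screening: interval
#' `i` is flagged when it deviates from its local median by more than
#' `tol` times that median, the local median being taken over up to `k`
#' unflagged preceding and `k` following intervals. Within each run of
#' flagged intervals, the interior beats are re-timed so the intervals follow
#' a cubic-spline prediction over beat index (fit to unflagged intervals),
#' rescaled to preserve the run's total duration -- so unflagged beat times
#' are bit-identical to the input and the number of beats never changes.
#' Re-timed beats are annotated `interpolated`.
#'
#' If the flagged-beat fraction reaches `maxFraction` (default 20%), or
#' corrected intervals still fall outside the 200-3000 ms plausibility gate
#' in such numbers that the combined fraction does, the series is rejected
#' as uncorrectable (condition class `uncorrectableSeries`, carrying the
#' observed fraction) -- the automated analogue of excluding a noise-ridden
#' recording from analysis.
#'
#' @param beats a [BeatSeries-class] with at least `2 k + 2` beats.
#' @param maxFraction rejection threshold on the flagged-beat fraction.
#' @param k local-window half-width (intervals each side).
#' @param tol relative deviation from the local median that flags an interval.
#' @return A corrected [BeatSeries-class].
#' @export
correctEctopics <- function(beats, maxFraction = 0.20, k = 5L, tol = 0.2) {
  validObject(beats)
  t <- beats@rTimes
  nb <- length(t)
  if (nb < 2L * k + 2L)
    stopData("need at least %d beats for ectopic screening", 2L * k + 2L)
  rr <- diff(t) * 1000
  ni <- length(rr)

  flagged <- logical(ni)
  for (i in seq_len(ni)) {
    prev <- which(!flagged[seq_len(i - 1L)])
    prev <- utils::tail(prev, k)
    nxt <- seq(i + 1L, length.out = min(k, ni - i))
    ref <- rr[c(prev, nxt)]
    if (length(ref) < 3L) next
    med <- stats::median(ref)
    if (abs(rr[i] - med) > tol * med) flagged[i] <- TRUE
  }

  # a lone flagged interval has no movable interior beat (both endpoints are
  # anchored by unflagged intervals); absorb a neighbouring interval so the
  # shared beat becomes correctable
  runs <- rle(flagged)
  ends0 <- cumsum(runs$lengths)
  starts0 <- ends0 - runs$lengths + 1L
  for (j in which(runs$values & runs$lengths == 1L)) {
    i <- starts0[j]
    if (i < ni) flagged[i + 1L] <- TRUE else flagged[i - 1L] <- TRUE
  }

  # interior beats of flagged runs are the correctable (and countable) ones
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  flaggedBeats <- integer(0)
  for (j in which(runs$values)) {
    if (runs$lengths[j] >= 2L)
      flaggedBeats <- c(flaggedBeats, (starts[j] + 1L):ends[j])
  }
  fraction <- length(flaggedBeats) / nb
  if (fraction >= maxFraction) {
    stop(errorCondition(
      sprintf("uncorrectable series: %.1f%% of beats flagged as ectopic (limit %.0f%%)",
              100 * fraction, 100 * maxFraction),
      fraction = fraction,
      class = c("uncorrectableSeries", "hrvDataError", "hrvError")))
  }

  ann <- beats@annotations
  if (any(flagged) && sum(!flagged) >= 4L) {
    good <- which(!flagged)
    for (j in which(runs$values)) {
      if (runs$lengths[j] < 2L) next
      i1 <- starts[j]; i2 <- ends[j]
      pred <- stats::spline(good, rr[good], xout = i1:i2, method = "fmm")$y
      gapMs <- (t[i2 + 1L] - t[i1]) * 1000
      pred <- pred * gapMs / sum(pred)
      newTimes <- t[i1] + cumsum(pred[-length(pred)]) / 1000
      idx <- (i1 + 1L):i2
      t[idx] <- newTimes
      ann[idx] <- "interpolated"
    }
  }

  rrNew <- diff(t) * 1000
  bad <- which(rrNew < 200 | rrNew > 3000)
  if (length(bad)) {
    combined <- (length(flaggedBeats) + length(unique(c(bad, bad + 1L)))) / nb
    if (combined >= maxFraction)
      stop(errorCondition(
        sprintf("uncorrectable series: %.1f%% of beats implausible or ectopic (limit %.0f%%)",
                100 * combined, 100 * maxFraction),
        fraction = combined,
        class = c("uncorrectableSeries", "hrvDataError", "hrvError")))
    warning(sprintf("%d corrected interval(s) remain outside the 200-3000 ms gate",
                    length(bad)))
  }
  new("BeatSeries", rTimes = t, annotations = ann)
}
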