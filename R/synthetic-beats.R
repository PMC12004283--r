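#' Generate beat times from a modulated heart-period model
#'
#' Integrate-and-fire realization on the instantaneous heart period: starting
#' at t = 0, each interval equals the model period evaluated at the current
#' beat, \eqn{m_0 + A_{LF}\sin(2\pi f_{LF} t) + A_{HF}\sin(2\pi f_{HF} t) +
#' \epsilon}, plus the condition shift \eqn{\delta} of the stimulus window
#' (if any) in which the *next* beat lands. Applying \eqn{\delta} at the
#' terminating beat makes the embedded condition effect exact under the
#' downstream convention that assigns an interval to the window containing
#' its terminating beat. Beats cover the full protocol span; all are
#' annotated `normal`.
#'
#' This is a test-surface generator, not a physiological simulator: it
#' produces band-limited heart-period variability and mean shifts with known
#' ground truth, nothing more.
#'
#' @param protocol a [SessionProtocol-class].
#' @param model a [HeartPeriodModel-class].
#' @param seed integer seed for the per-beat white noise.
#' @return A [BeatSeries-class].
#' @export
#' @examples
#' p <- generateProtocol(seed = 1)
#' m <- new("HeartPeriodModel", aLF = 0, aHF = 0, sigma = 0,
#'          delta = c(acquaintance = 0, stranger = 0), m0 = 1000)
#' b <- generateBeats(p, m, seed = 1)
#' unique(round(rrIntervals(b), 9))
generateBeats <- function(protocol, model, seed) {
  validObject(protocol); validObject(model)
  span <- sessionDuration(protocol)
  stimTab <- stimulusTable(protocol)
  delta <- model@delta
  dmin <- if (length(delta)) min(delta, 0) else 0
  if (model@m0 - model@aLF - model@aHF + dmin <= 0)
    stopData("heart period can reach zero: m0 too small for the modulation")

  withSeed(seed, {
    nGuess <- ceiling(span / (model@m0 / 1000) * 1.5) + 16L
    noise <- if (model@sigma > 0) stats::rnorm(nGuess, 0, model@sigma)
             else numeric(nGuess)
    t <- numeric(nGuess + 1L)
    k <- 1L
    wLF <- 2 * pi * model@fLF; wHF <- 2 * pi * model@fHF
    dNames <- names(delta)
    repeat {
      tk <- t[k]
      p0 <- model@m0 + model@aLF * sin(wLF * tk) +
        model@aHF * sin(wHF * tk) + noise[k]
      if (p0 <= 0)
        stopData("instantaneous heart period <= 0 at t = %.2f s", tk)
      te <- tk + p0 / 1000
      cond <- conditionAt(te, stimTab)
      p <- p0
      if (cond != "none" && cond %in% dNames) p <- p0 + delta[[cond]]
      if (p <= 0)
        stopData("instantaneous heart period <= 0 at t = %.2f s", tk)
      t[k + 1L] <- tk + p / 1000
      k <- k + 1L
      if (t[k] >= span) break
      if (k > nGuess) {  # slow heart period drifted: extend noise buffer
        noise <- c(noise, if (model@sigma > 0)
          stats::rnorm(nGuess, 0, model@sigma) else numeric(nGuess))
        t <- c(t, numeric(nGuess))
        nGuess <- length(noise)
      }
    }
    t <- t[seq_len(k)]
    new("BeatSeries", rTimes = t, annotations = rep("normal", k))
  })
}

#' Inject ground-truth ectopic beats
#'
#' Displaces a seeded, non-adjacent selection of `floor(fraction * n)` beats
#' early, to 0.6 times the preceding interval, leaving the following beat
#' untouched (compensatory pause). On a regular series this turns one
#' interval pair into (0.6, 1.4) times the base interval -- the classic
#' premature-beat signature -- while preserving total beat count and all
#' other beat times. Displaced beats are annotated `ectopic`, giving the
#' correction stage a ground truth to be scored against.
#'
#' @param beats a [BeatSeries-class].
#' @param fraction proportion of beats to displace, in `[0, 1)`.
#' @param seed integer seed for the selection.
#' @return A [BeatSeries-class] with the same number of beats.
#' @export
injectEctopics <- function(beats, fraction, seed) {
  validObject(beats)
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 0 || fraction >= 1)
    stopConfig("fraction must lie in [0, 1) (got %s)", deparse(fraction))
  n <- length(beats@rTimes)
  k <- floor(fraction * n)
  if (k == 0L) return(beats)
  eligible <- seq(2L, n - 1L)
  chosen <- withSeed(seed, {
    pool <- sample(eligible)
    sel <- integer(0)
    for (j in pool) {
      if (length(sel) == k) break
      if (!any(abs(sel - j) <= 1L)) sel <- c(sel, j)
    }
    sel
  })
  if (length(chosen) < k)
    stopData("cannot place %d non-adjacent ectopics among %d beats", k, n)
  t <- beats@rTimes
  ann <- beats@annotations
  for (j in sort(chosen)) {
    t[j] <- t[j - 1L] + 0.6 * (t[j] - t[j - 1L])
    ann[j] <- "ectopic"
  }
  new("BeatSeries", rTimes = t, annotations = ann)
}
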