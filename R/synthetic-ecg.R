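# P-QRS-T template: sum of Gaussian deflections (amplitudes in mV, centers
# and widths in s relative to the R peak). The R wave dominates so the
# sample argmax of a clean record sits at the beat time.
ecgTemplate <- function(dt) {
  amp <- c(P = 0.15, Q = -0.10, R = 1.00, S = -0.15, T = 0.30)
  mu  <- c(P = -0.200, Q = -0.028, R = 0.000, S = 0.028, T = 0.250)
  sd  <- c(P = 0.025, Q = 0.008, R = 0.010, S = 0.008, T = 0.060)
  v <- numeric(length(dt))
  for (w in names(amp))
    v <- v + amp[[w]] * exp(-0.5 * ((dt - mu[[w]]) / sd[[w]])^2)
  v
}

#' Synthesize an ECG waveform from beat times
#'
#' Places a fixed P-QRS-T template (1 mV R deflection) at every beat time and
#' adds the contamination the preprocessing chain is designed to remove:
#' sinusoidal baseline wander, 50 Hz mains interference, and white noise.
#' The record runs from one second before the first beat (so the edge beats
#' have a fully represented template; `t0` is set accordingly) to one second
#' after the last.
#'
#' @param beats a [BeatSeries-class].
#' @param fs sampling rate (Hz), at least 128 so the QRS is representable.
#' @param noise list with elements `wanderAmp` (mV), `wanderFreq` (Hz),
#'   `mainsAmp` (mV), `whiteSd` (mV); missing elements default to 0.
#' @param seed integer seed for the white noise and wander/mains phases.
#' @return An [ECGRecord-class] starting at t0 = 0.
#' @export
#' @examples
#' b <- new("BeatSeries", rTimes = seq(0, 10, by = 0.8),
#'          annotations = rep("normal", 13))
#' synthesizeECG(b, fs = 256, noise = list(), seed = 1)
synthesizeECG <- function(beats, fs = 256,
                          noise = list(wanderAmp = 0, wanderFreq = 0.25,
                                       mainsAmp = 0, whiteSd = 0),
                          seed = 1L) {
  validObject(beats)
  if (fs < 128)
    stopConfig("fs = %g Hz is too low to represent the QRS template", fs)
  get0n <- function(nm) if (is.null(noise[[nm]])) 0 else noise[[nm]]
  wanderAmp <- get0n("wanderAmp"); wanderFreq <- get0n("wanderFreq")
  mainsAmp <- get0n("mainsAmp"); whiteSd <- get0n("whiteSd")

  # 1-s lead-in/out so edge beats have a fully represented template
  tStart <- min(beats@rTimes) - 1
  tEnd <- max(beats@rTimes) + 1
  n <- ceiling((tEnd - tStart) * fs) + 1L
  tt <- tStart + (seq_len(n) - 1L) / fs
  x <- numeric(n)
  halfWidth <- 0.45  # template support (s) around each beat
  for (bt in beats@rTimes) {
    i0 <- max(1L, floor((bt - halfWidth - tStart) * fs) + 1L)
    i1 <- min(n, ceiling((bt + halfWidth - tStart) * fs) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + ecgTemplate(tt[idx] - bt)
  }
  withSeed(seed, {
    if (wanderAmp > 0 && wanderFreq > 0)
      x <- x + wanderAmp * sin(2 * pi * wanderFreq * tt +
                               stats::runif(1, 0, 2 * pi))
    if (mainsAmp > 0)
      x <- x + mainsAmp * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
    if (whiteSd > 0)
      x <- x + stats::rnorm(n, 0, whiteSd)
    x
  }) -> x
  new("ECGRecord", samples = x, fs = fs, t0 = tStart, label = "synthetic")
}
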