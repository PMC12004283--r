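# Welch power spectral density with Hann taper. For the 55-s protocol
# windows a single full-length segment is used (no averaging is possible at
# that duration); longer series can be split via segLength/overlap.
# Returns one-sided PSD in input-units^2 per Hz.
welchPsd <- function(x, fs, segLength = length(x), overlap = 0.5) {
  n <- length(x)
  segLength <- min(segLength, n)
  step <- max(1L, floor(segLength * (1 - overlap)))
  starts <- seq(1L, n - segLength + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / (segLength + 1))  # Hann
  u <- sum(w^2)
  nf <- floor(segLength / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- (Mod(X[seq_len(nf)])^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even lengths)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (segLength %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / segLength,
       psd = acc / length(starts))
}

bandPower <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (!any(sel)) return(0)
  df <- if (length(freq) > 1L) freq[2L] - freq[1L] else 0
  sum(psd[sel]) * df
}

#' Frequency-domain HRV measures of one R-R series
#'
#' The tachogram (R-R interval vs. time of the terminating beat) is
#' interpolated to a uniform 4 Hz grid with a cubic spline, mean-detrended,
#' and its power spectral density estimated by Welch's method with a Hann
#' taper (a single full-window segment at the 55-s protocol duration). `HF`
#' is the integrated power over the high-frequency band 0.15-0.4 Hz (ms^2),
#' reflecting respiratory-frequency vagal modulation; `HFn` normalizes it by
#' the total 0.04-0.4 Hz power. Windows shorter than 120 s carry a
#' low-reliability flag because the low-frequency part of the denominator is
#' under-resolved at ultra-short durations; a zero-variance series yields
#' HF = 0, HFn = 0 with a degenerate flag.
#'
#' @param rr R-R intervals (ms).
#' @param beatTimes beat times (s), one more than `length(rr)`; interval `i`
#'   is stamped at its terminating beat `beatTimes[i + 1]`.
#' @param resampleFs uniform grid rate (Hz).
#' @param segLength,overlap Welch segmentation (defaults: one full segment).
#' @return List with `HF` (ms^2), `HFn` (0-1), and logical flags
#'   `lowReliability`, `degenerate`.
#' @export
frequencyDomainFeatures <- function(rr, beatTimes, resampleFs = 4,
                                    segLength = NULL, overlap = 0.5) {
  if (length(beatTimes) != length(rr) + 1L)
    stopData("beatTimes must have one more element than rr")
  if (length(rr) < 10L)
    stopData("need at least 10 intervals for spectral analysis (got %d)",
             length(rr))
  span <- beatTimes[length(beatTimes)] - beatTimes[1L]
  if (span < 30)
    stopData("window span %.1f s too short for spectral analysis", span)
  tTach <- beatTimes[-1L]
  if (stats::sd(rr) < .Machine$double.eps * 1e3 * max(abs(rr), 1)) {
    return(list(HF = 0, HFn = 0, lowReliability = span < 120,
                degenerate = TRUE))
  }
  grid <- seq(tTach[1L], tTach[length(tTach)], by = 1 / resampleFs)
  xi <- stats::spline(tTach, rr, xout = grid, method = "fmm")$y
  if (is.null(segLength)) segLength <- length(xi)
  ps <- welchPsd(xi, fs = resampleFs, segLength = segLength,
                 overlap = overlap)
  hf <- bandPower(ps$freq, ps$psd, 0.15, 0.4)
  tot <- bandPower(ps$freq, ps$psd, 0.04, 0.4)
  if (tot <= 0) {
    return(list(HF = 0, HFn = 0, lowReliability = span < 120,
                degenerate = TRUE))
  }
  list(HF = hf, HFn = hf / tot, lowReliability = span < 120,
       degenerate = FALSE)
}
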