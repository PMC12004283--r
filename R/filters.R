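# Zero-phase IIR filtering with odd-reflection edge padding. Forward-backward
# application squares the magnitude response and cancels phase, preserving
# R-peak timing; padding suppresses the start/end transients that a plain
# forward-backward pass leaves on finite records.
zerophaseFilter <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3L * (max(length(a), length(b)) - 1L)
  padlen <- min(padlen, n - 1L)
  xp <- c(2 * x[1L] - x[(padlen + 1L):2L],
          x,
          2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(padlen + 1L):(padlen + n)])
}

# FFT-based resampling (band-limited interpolation): the spectrum is
# truncated or zero-padded to the new length. Near-exact in the passband for
# band-limited signals, unlike short-FIR polyphase schemes.
fftResample <- function(x, n2) {
  n <- length(x)
  if (n2 == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n2)
  k <- floor(min(n, n2) / 2)
  Y[1:(k + 1L)] <- X[1:(k + 1L)]
  if (k > 0) Y[(n2 - k + 1L):n2] <- X[(n - k + 1L):n]
  if (min(n, n2) %% 2 == 0 && k > 0) {
    # split the Nyquist bin symmetrically to keep the result real
    Y[k + 1L] <- Y[k + 1L] / 2
    Y[n2 - k + 1L] <- Y[n2 - k + 1L] + Conj(Y[k + 1L])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample an ECG record
#'
#' Band-limited (FFT) resampling to `targetFs`, the pipeline default being
#' 256 Hz. Duration is preserved to within one sample period; a record
#' already at the target rate passes through unchanged.
#'
#' @param record an [ECGRecord-class].
#' @param targetFs target sampling rate (Hz).
#' @return An [ECGRecord-class] at `targetFs`.
#' @export
resampleECG <- function(record, targetFs = 256) {
  validObject(record)
  if (length(record@samples) == 0L) stopData("empty record")
  if (targetFs <= 0) stopConfig("targetFs must be positive")
  if (targetFs == record@fs) return(record)
  n2 <- round(length(record@samples) * targetFs / record@fs)
  new("ECGRecord", samples = fftResample(record@samples, n2),
      fs = targetFs, t0 = record@t0, label = record@label)
}

#' High-pass filter an ECG record
#'
#' Butterworth high-pass (default 5th order, 0.5 Hz cutoff) removing DC
#' offset and respiration-related baseline wander. Applied zero-phase
#' (forward-backward) by default so R-peak timing is untouched; the
#' effective magnitude response is then the squared single-pass response.
#'
#' @param record an [ECGRecord-class] with at least 2 s of data.
#' @param order filter order (single pass).
#' @param fc cutoff frequency (Hz).
#' @param zeroPhase apply forward-backward (TRUE) or single-pass causal.
#' @return A filtered [ECGRecord-class].
#' @export
highpassECG <- function(record, order = 5L, fc = 0.5, zeroPhase = TRUE) {
  validObject(record)
  if (record@fs <= 2 * fc)
    stopData("sampling rate %g Hz too low for a %g Hz high-pass",
             record@fs, fc)
  if (length(record@samples) < 2 * record@fs)
    stopData("record shorter than 2 s; filtering is unreliable")
  bw <- signal::butter(order, fc / (record@fs / 2), type = "high")
  y <- if (zeroPhase) {
    # pad over several cutoff periods: the 0.5 Hz transient is long
    zerophaseFilter(bw$b, bw$a, record@samples,
                    padlen = ceiling(3 * record@fs / fc))
  } else {
    as.numeric(signal::filter(bw, record@samples))
  }
  new("ECGRecord", samples = y, fs = record@fs, t0 = record@t0,
      label = record@label)
}

#' Notch filter an ECG record
#'
#' Narrow IIR band-stop at `f0` (default 50 Hz) suppressing power-line
#' interference, applied zero-phase. The stop band half-width is
#' `f0 / (2 q)`; the default quality factor 30 attenuates a pure 50 Hz tone
#' by well over 20 dB while leaving the 5-15 Hz QRS band untouched.
#'
#' @param record an [ECGRecord-class].
#' @param f0 notch center frequency (Hz).
#' @param q quality factor (center / bandwidth).
#' @param zeroPhase apply forward-backward (TRUE) or single-pass causal.
#' @return A filtered [ECGRecord-class].
#' @export
notchECG <- function(record, f0 = 50, q = 30, zeroPhase = TRUE) {
  validObject(record)
  if (record@fs <= 2 * f0)
    stopData("sampling rate %g Hz too low for a %g Hz notch", record@fs, f0)
  if (length(record@samples) < 2 * record@fs)
    stopData("record shorter than 2 s; filtering is unreliable")
  bw <- f0 / q
  edges <- c(f0 - bw / 2, f0 + bw / 2) / (record@fs / 2)
  flt <- signal::butter(2, edges, type = "stop")
  y <- if (zeroPhase) {
    zerophaseFilter(flt$b, flt$a, record@samples,
                    padlen = ceiling(record@fs / 2))
  } else {
    as.numeric(signal::filter(flt, record@samples))
  }
  new("ECGRecord", samples = y, fs = record@fs, t0 = record@t0,
      label = record@label)
}
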