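#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic QRS detection chain: 5-15 Hz Butterworth band-pass (zero-phase),
#' five-point derivative, squaring, 150-ms moving-window integration, then
#' dual adaptive thresholds with running signal/noise peak estimates, a
#' 200-ms refractory period, and a search-back pass triggered when no QRS is
#' found within 1.66 times the running R-R estimate. Accepted fiducials are
#' refined to the local maximum of the (band-passed) ECG within +/- 50 ms,
#' a deterministic stand-in for the manual inspection step usual in
#' HRV practice.
#'
#' @param record an [ECGRecord-class], at least 5 s long; may be raw or
#'   already high-pass/notch filtered (the detector applies its own
#'   band-pass).
#' @param refineOn refine fiducials on the `"record"` samples (default;
#'   appropriate when the input is already baseline-free) or on the
#'   internal `"bandpass"` signal.
#' @return A [BeatSeries-class] with all beats annotated `normal`. Beat
#'   times are relative to the record's `t0`.
#' @export
detectRPeaks <- function(record, refineOn = c("record", "bandpass")) {
  validObject(record)
  refineOn <- match.arg(refineOn)
  fs <- record@fs
  x <- record@samples
  n <- length(x)
  if (n < 5 * fs) stopData("record shorter than 5 s; detection rejected")

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xb <- zerophaseFilter(bp$b, bp$a, x, padlen = ceiling(fs))
  # five-point derivative (zero-phase, centered)
  dcoef <- c(1, 2, 0, -2, -1) * fs / 8
  xd <- as.numeric(stats::filter(xb, dcoef, sides = 2))
  xd[is.na(xd)] <- 0
  xs <- xd^2
  wI <- max(3L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(xs, rep(1 / wI, wI), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal, >= 200 ms apart
  refr <- round(0.200 * fs)
  isMax <- mwi > c(-Inf, mwi[-n]) & mwi >= c(mwi[-1L], -Inf) & mwi > 0
  cand <- which(isMax)
  if (length(cand) > 1L) {
    keep <- logical(length(cand))
    last <- -Inf
    ord <- seq_along(cand)
    for (i in ord) {
      if (cand[i] - last >= refr) { keep[i] <- TRUE; last <- cand[i] }
      else if (mwi[cand[i]] > mwi[last]) { keep[which(cand == last)] <- FALSE
        keep[i] <- TRUE; last <- cand[i] }
    }
    cand <- cand[keep]
  }
  if (length(cand) < 3L) stopData("fewer than 3 candidate beats detected")

  init <- mwi[seq_len(min(n, 2L * round(fs)))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  noisePk <- integer(0)
  rrBuf <- numeric(0)
  for (i in seq_along(cand)) {
    pk <- cand[i]; v <- mwi[pk]
    accepted <- FALSE
    if (v > thr1 && (length(qrs) == 0L || pk - qrs[length(qrs)] > refr)) {
      qrs <- c(qrs, pk)
      spki <- 0.125 * v + 0.875 * spki
      accepted <- TRUE
    } else {
      noisePk <- c(noisePk, pk)
      npki <- 0.125 * v + 0.875 * npki
    }
    if (accepted && length(qrs) >= 2L) {
      rrBuf <- c(rrBuf, qrs[length(qrs)] - qrs[length(qrs) - 1L])
      if (length(rrBuf) > 8L) rrBuf <- rrBuf[-1L]
    }
    # search-back: a long gap without QRS re-examines skipped peaks at thr2
    if (length(qrs) >= 1L && length(rrBuf) >= 2L) {
      gap <- pk - qrs[length(qrs)]
      if (!accepted && gap > 1.66 * mean(rrBuf)) {
        inGap <- noisePk[noisePk > qrs[length(qrs)] & noisePk <= pk]
        inGap <- inGap[mwi[inGap] > 0.5 * thr1]
        if (length(inGap)) {
          sb <- inGap[which.max(mwi[inGap])]
          if (sb - qrs[length(qrs)] > refr) {
            qrs <- sort(c(qrs, sb))
            spki <- 0.25 * mwi[sb] + 0.75 * spki
            rrBuf <- c(rrBuf, gap)
            if (length(rrBuf) > 8L) rrBuf <- rrBuf[-1L]
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(qrs) < 3L) stopData("fewer than 3 beats detected")

  # refine each fiducial to the local ECG maximum within +/- 50 ms
  ref <- if (refineOn == "record") x else xb
  half <- as.integer(round(0.050 * fs))
  peaks <- vapply(as.integer(qrs), function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(ref[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  tPk <- record@t0 + (peaks - 1L) / fs
  new("BeatSeries", rTimes = tPk,
      annotations = rep("normal", length(tPk)))
}
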