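#' Time-domain HRV measures of one R-R series
#'
#' The ten time-domain measures computed on a single window's R-R intervals:
#' location (MeanNN, MedianNN, Prc80NN, Prc20NN, all ms), dispersion (MadNN =
#' 1.4826 times the median absolute deviation, SDNN = sample SD, both ms),
#' and beat-to-beat variability from the successive differences `d = diff(rr)`
#' (RMSSD, SDSD in ms; pNN20 / pNN50 = percentage of `|d|` strictly above
#' 20 / 50 ms). Percentiles use linear interpolation between order statistics;
#' SD uses the n-1 denominator.
#'
#' @param rr R-R intervals (ms), at least 4, all positive.
#' @param madConstant scale factor applied to the median absolute deviation;
#'   1.4826 (default) makes MadNN consistent with the SD under normality, 1
#'   gives the raw MAD.
#' @return Named list of the ten time-domain measures.
#' @export
#' @examples
#' timeDomainFeatures(c(800, 810, 790, 830))
timeDomainFeatures <- function(rr, madConstant = 1.4826) {
  if (length(rr) < 4L)
    stopData("need at least 4 intervals (got %d)", length(rr))
  if (any(!is.finite(rr)) || any(rr <= 0))
    stopData("R-R intervals must be positive and finite")
  d <- diff(rr)
  list(
    MeanNN = mean(rr),
    MedianNN = stats::median(rr),
    MadNN = stats::mad(rr, constant = madConstant),
    SDNN = stats::sd(rr),
    RMSSD = sqrt(mean(d^2)),
    SDSD = stats::sd(d),
    Prc80NN = unname(stats::quantile(rr, 0.80, type = 7)),
    Prc20NN = unname(stats::quantile(rr, 0.20, type = 7)),
    pNN20 = 100 * mean(abs(d) > 20),
    pNN50 = 100 * mean(abs(d) > 50)
  )
}
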