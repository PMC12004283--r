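matchStats <- function(truth, detected, tolSec = 0.010) {
  sens <- mean(vapply(truth, function(x) min(abs(detected - x)),
                      numeric(1)) <= tolSec)
  ppv <- mean(vapply(detected, function(x) min(abs(truth - x)),
                     numeric(1)) <= tolSec)
  c(sensitivity = sens, ppv = ppv)
}

test_that("clean synthetic ECG at 80 bpm is detected perfectly", {
  truth <- seq(0, 60, by = 0.75)
  b <- new("BeatSeries", rTimes = truth,
           annotations = rep("normal", length(truth)))
  ecg <- synthesizeECG(b, fs = 256, noise = list(), seed = 1)
  det <- detectRPeaks(ecg)
  st <- matchStats(truth, rTimes(det))
  expect_equal(unname(st["sensitivity"]), 1)
  expect_equal(unname(st["ppv"]), 1)
})

test_that("detection survives moderate noise across 50-120 bpm", {
  for (bpm in c(50, 70, 90, 120)) {
    truth <- seq(0, 60, by = 60 / bpm)
    b <- new("BeatSeries", rTimes = truth,
             annotations = rep("normal", length(truth)))
    ecg <- synthesizeECG(b, fs = 512,
                         noise = list(wanderAmp = 0.3, wanderFreq = 0.25,
                                      mainsAmp = 0.1, whiteSd = 0.05),
                         seed = bpm)
    det <- preprocessECG(ecg)
    st <- matchStats(truth, rTimes(det))
    expect_gte(unname(st["sensitivity"]), 0.99)
    expect_gte(unname(st["ppv"]), 0.99)
    # beat count within 1 of truth on the full preprocessing chain
    expect_lte(abs(length(rTimes(det)) - length(truth)), 1)
  }
})

test_that("degenerate records are rejected", {
  flat <- new("ECGRecord", samples = numeric(256 * 10), fs = 256, t0 = 0,
              label = "flat")
  expect_error(detectRPeaks(flat), "beats|candidate")
  short <- new("ECGRecord", samples = rnorm(256 * 2), fs = 256, t0 = 0,
               label = "short")
  expect_error(detectRPeaks(short), "shorter")
})

test_that("detection after preprocessing recovers window-mean R-R", {
  p <- generateProtocol(seed = 4, nStimuli = 2)
  m <- quietModel(m0 = 850, sigma = 10,
                  delta = c(acquaintance = 25, stranger = 0))
  truthBeats <- generateBeats(p, m, seed = 4)
  ecg <- synthesizeECG(truthBeats, fs = 256,
                       noise = list(wanderAmp = 0.2, wanderFreq = 0.25,
                                    mainsAmp = 0.05, whiteSd = 0.05),
                       seed = 4)
  det <- preprocessECG(ecg)
  ev <- events(p)
  for (i in seq_len(nrow(ev))) {
    w <- c(ev$onset[i], ev$onset[i] + ev$duration[i])
    truthSel <- rTimes(truthBeats)[-1] >= w[1] & rTimes(truthBeats)[-1] < w[2]
    detSel <- rTimes(det)[-1] >= w[1] & rTimes(det)[-1] < w[2]
    expect_lt(abs(mean(rrIntervals(truthBeats)[truthSel]) -
                  mean(rrIntervals(det)[detSel])), 2)
  }
})
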