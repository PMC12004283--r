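# Fixture builders shared by the tests.

regularBeats <- function(n = 100, rrSec = 1) {
  t <- seq(0, by = rrSec, length.out = n)
  new("BeatSeries", rTimes = t, annotations = rep("normal", n))
}

quietModel <- function(m0 = 1000, delta = c(acquaintance = 0, stranger = 0),
                       sigma = 0, aLF = 0, aHF = 0) {
  new("HeartPeriodModel", m0 = m0, aLF = aLF, aHF = aHF,
      fLF = 0.1, fHF = 0.25, sigma = sigma, delta = delta)
}

# Small cohort spec for fast end-to-end tests.
tinySpec <- function(seed = 1L, nHC = 3L, nMCS = 1L, nUWS = 1L, ...) {
  cohortSpec(nPerGroup = c(HC = nHC, MCS = nMCS, UWS = nUWS),
             seed = seed, ...)
}

meanRRInWindows <- function(beats, protocol, cond) {
  ev <- events(protocol)
  st <- ev[ev$label == "stimulus" & ev$condition == cond, ]
  t <- rTimes(beats); term <- t[-1]; rr <- diff(t) * 1000
  vals <- c()
  for (i in seq_len(nrow(st))) {
    sel <- term >= st$onset[i] & term < st$onset[i] + st$duration[i]
    vals <- c(vals, rr[sel])
  }
  vals
}
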