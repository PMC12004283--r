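test_that("constant heart period gives constant R-R intervals", {
  p <- generateProtocol(seed = 1)
  b <- generateBeats(p, quietModel(m0 = 1000), seed = 1)
  expect_equal(unique(rrIntervals(b)), 1000)
  expect_true(all(annotations(b) == "normal"))
  expect_gte(max(rTimes(b)), sessionDuration(p))
})

test_that("condition shifts embed exactly in window-mean R-R", {
  p <- generateProtocol(seed = 1)
  m <- quietModel(m0 = 800, delta = c(acquaintance = 40, stranger = 0))
  b <- generateBeats(p, m, seed = 1)
  acq <- meanRRInWindows(b, p, "acquaintance")
  str <- meanRRInWindows(b, p, "stranger")
  expect_lt(max(abs(acq - 840)), 1e-9)
  expect_lt(max(abs(str - 800)), 1e-9)
  expect_equal(mean(acq) - mean(str), 40, tolerance = 1e-9)
})

test_that("HF-only modulation concentrates tachogram power in 0.15-0.4 Hz", {
  # 300-s flat protocol span via a 2-stimulus session is too short; use the
  # default session and take the first 300 s of beats
  p <- generateProtocol(seed = 1)
  m <- quietModel(m0 = 900)
  m@aHF <- 30; m@fHF <- 0.3
  b <- generateBeats(p, m, seed = 2)
  keep <- rTimes(b) <= 300
  t <- rTimes(b)[keep]
  rr <- diff(t) * 1000
  fd <- frequencyDomainFeatures(rr, t)
  expect_gte(fd$HFn, 0.8)
  # direct periodogram oracle: spectral maximum falls in the HF band
  grid <- seq(t[2], t[length(t)], by = 0.25)
  xi <- stats::spline(t[-1], rr, xout = grid)$y
  sp <- stats::spec.pgram(stats::ts(xi - mean(xi), frequency = 4),
                          plot = FALSE, taper = 0)
  inBand <- sp$freq >= 0.04 & sp$freq <= 0.4
  fmax <- sp$freq[inBand][which.max(sp$spec[inBand])]
  expect_true(fmax >= 0.15 && fmax <= 0.4)
})

test_that("beat generation is seed-deterministic and count-sane", {
  p <- generateProtocol(seed = 1)
  m <- quietModel(m0 = 850, sigma = 10)
  expect_identical(generateBeats(p, m, seed = 7), generateBeats(p, m, seed = 7))
  for (m0 in c(600, 850, 1100)) {
    b <- generateBeats(p, quietModel(m0 = m0, sigma = 5), seed = 3)
    expected <- sessionDuration(p) / (m0 / 1000)
    expect_lt(abs(length(rTimes(b)) - expected) / expected, 0.05)
  }
})

test_that("non-positive heart periods are rejected", {
  p <- generateProtocol(seed = 1)
  m <- quietModel(m0 = 100)
  m@aLF <- 80; m@aHF <- 80  # envelope can cross zero
  expect_error(generateBeats(p, m, seed = 1), "period")
})

test_that("ectopic injection follows the premature-beat rule", {
  b <- regularBeats(100, 1)
  expect_identical(injectEctopics(b, 0, seed = 1), b)
  bi <- injectEctopics(b, 0.1, seed = 1)
  expect_equal(sum(annotations(bi) == "ectopic"), 10L)
  expect_equal(length(rTimes(bi)), 100L)
  # non-adjacent: no two consecutive beats displaced
  idx <- which(annotations(bi) == "ectopic")
  expect_true(all(diff(idx) >= 2L))
  # local interval pair around one injection is (600, 1400) ms
  j <- idx[1]
  rr <- rrIntervals(bi)
  expect_equal(rr[j - 1L], 600)
  expect_equal(rr[j], 1400)
  # downstream beat times preserved
  expect_identical(rTimes(bi)[-idx], rTimes(b)[-idx])
  expect_error(injectEctopics(b, 1, seed = 1), "fraction")
})

test_that("cohort generation is deterministic with group-scaled effects", {
  spec <- tinySpec(seed = 5)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(c1, c2)
  expect_equal(vapply(c1, `[[`, character(1), "group"),
               c("HC", "HC", "HC", "MCS", "UWS"))
  # patient groups have the condition effect silenced
  for (subj in c1[4:5]) {
    acq <- meanRRInWindows(subj$beats, subj$protocol, "acquaintance")
    str <- meanRRInWindows(subj$beats, subj$protocol, "stranger")
    # sigma=10 noise: means differ only by sampling error, not by 25 ms
    expect_lt(abs(mean(acq) - mean(str)), 10)
  }
  spec28 <- cohortSpec(seed = 2)
  expect_equal(sum(vapply(generateCohort(spec28), `[[`, character(1),
                          "group") == "HC"), 17L)
})
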