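mkRecord <- function(x, fs) new("ECGRecord", samples = x, fs = fs, t0 = 0,
                                label = "test")

test_that("resampling preserves duration and reproduces sinusoids", {
  fs <- 512
  rec <- mkRecord(rnorm(fs * 10), fs)
  out <- resampleECG(rec, 256)
  expect_equal(length(samples(out)), 2560L)
  expect_equal(samplingRate(out), 256)

  t1 <- (0:(1000 * 10 - 1)) / 1000
  rec <- mkRecord(sin(2 * pi * 10 * t1), 1000)
  out <- resampleECG(rec, 256)
  t2 <- (0:(length(samples(out)) - 1)) / 256
  expect_lt(max(abs(samples(out) - sin(2 * pi * 10 * t2))), 0.01)

  rec <- mkRecord(rnorm(256 * 3), 256)
  expect_identical(samples(resampleECG(rec, 256)), samples(rec))
  expect_error(resampleECG(mkRecord(numeric(0), 256)), "empty")
})

test_that("high-pass removes DC and matches the Butterworth response", {
  fs <- 256
  n <- fs * 60
  rec <- mkRecord(rep(2.5, n), fs)
  out <- highpassECG(rec)
  expect_lt(abs(mean(samples(out))) / 2.5, 0.01)

  tt <- (0:(n - 1)) / fs
  # stop band: 0.2 Hz attenuated at least as much as the squared single-pass
  # closed-form magnitude (zero-phase = two passes)
  rec <- mkRecord(sin(2 * pi * 0.2 * tt), fs)
  out <- samples(highpassECG(rec))
  interior <- seq(10 * fs, n - 10 * fs)
  expected <- butterHighpassMag(0.2, 0.5, 5)^2
  expect_lt(max(abs(out[interior])), 1.5 * expected)
  expect_lt(max(abs(out[interior])), 0.011)  # >= 10x the 0.2 Hz wander oracle

  # pass band: 20 Hz preserved within 2%
  rec <- mkRecord(sin(2 * pi * 20 * tt), fs)
  out <- samples(highpassECG(rec))
  expect_lt(abs(max(abs(out[interior])) - 1), 0.02)
})

test_that("notch suppresses 50 Hz by 20 dB and spares 10 Hz", {
  fs <- 256
  n <- fs * 30
  tt <- (0:(n - 1)) / fs
  x50 <- sin(2 * pi * 50 * tt)
  out <- samples(notchECG(mkRecord(x50, fs)))
  rms <- function(v) sqrt(mean(v^2))
  interior <- seq(5 * fs, n - 5 * fs)
  expect_lt(rms(out[interior]) / rms(x50[interior]), 0.1)  # >= 20 dB

  x10 <- sin(2 * pi * 10 * tt)
  out <- samples(notchECG(mkRecord(x10, fs)))
  expect_lt(abs(rms(out[interior]) / rms(x10[interior]) - 1), 0.02)

  out <- samples(notchECG(mkRecord(numeric(fs * 3), fs)))
  expect_equal(out, numeric(fs * 3))
  expect_error(notchECG(mkRecord(rnorm(500), 80)), "too low")
})

test_that("filtering is linear", {
  fs <- 256
  set.seed(42)
  x <- rnorm(fs * 10)
  a <- 3.7
  for (f in list(function(r) highpassECG(r), function(r) notchECG(r))) {
    y1 <- samples(f(mkRecord(a * x, fs)))
    y2 <- a * samples(f(mkRecord(x, fs)))
    # narrow-band IIR recursions amplify roundoff; linearity holds to ~1e-7
    expect_lt(max(abs(y1 - y2)), 1e-5 * max(abs(y2)))
  }
})
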