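test_that("constant series collapses all dispersion measures to zero", {
  td <- timeDomainFeatures(rep(1000, 4))
  expect_equal(td$MeanNN, 1000)
  expect_equal(td$MedianNN, 1000)
  expect_equal(td$Prc80NN, 1000)
  expect_equal(td$Prc20NN, 1000)
  expect_equal(td$MadNN, 0)
  expect_equal(td$SDNN, 0)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$SDSD, 0)
  expect_equal(td$pNN20, 0)
  expect_equal(td$pNN50, 0)
})

test_that("the worked toy series gives the hand-computed values", {
  td <- timeDomainFeatures(c(800, 810, 790, 830))
  # d = (10, -20, 40): RMSSD = sqrt((100+400+1600)/3)
  expect_equal(td$RMSSD, sqrt(2100 / 3), tolerance = 1e-12)
  expect_equal(td$pNN20, 100 / 3, tolerance = 1e-12)  # strict > 20
  expect_equal(td$pNN50, 0)
  expect_equal(td$MeanNN, 807.5)
})

test_that("time-domain features match a naive oracle on 1000 random series", {
  set.seed(101)
  for (i in seq_len(1000)) {
    n <- sample(20:120, 1)
    rr <- 800 + stats::rnorm(n, 0, 50)
    got <- timeDomainFeatures(rr)
    want <- naiveTimeDomain(rr)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   label = sprintf("%s (series %d)", f, i))
  }
})

test_that("reversal, shift and scale symmetries hold", {
  set.seed(7)
  rr <- 900 + stats::rnorm(40, 0, 60)
  a <- timeDomainFeatures(rr)
  b <- timeDomainFeatures(rev(rr))
  expect_equal(a, b, tolerance = 1e-12)

  cShift <- 120
  s <- timeDomainFeatures(rr + cShift)
  for (f in c("MeanNN", "MedianNN", "Prc80NN", "Prc20NN"))
    expect_equal(s[[f]], a[[f]] + cShift, tolerance = 1e-9)
  for (f in c("MadNN", "SDNN", "RMSSD", "SDSD", "pNN20", "pNN50"))
    expect_equal(s[[f]], a[[f]], tolerance = 1e-9)

  k <- 1.5
  sc <- timeDomainFeatures(rr * k)
  for (f in c("MeanNN", "MedianNN", "Prc80NN", "Prc20NN", "MadNN", "SDNN",
              "RMSSD", "SDSD"))
    expect_equal(sc[[f]], a[[f]] * k, tolerance = 1e-9)
})

test_that("pNN20 dominates pNN50 on arbitrary series", {
  set.seed(11)
  for (i in 1:50) {
    rr <- 800 + stats::rnorm(30, 0, sample(c(5, 20, 80), 1))
    td <- timeDomainFeatures(rr)
    expect_gte(td$pNN20, td$pNN50)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(timeDomainFeatures(c(800, 810, 790)), "at least 4")
  expect_error(timeDomainFeatures(c(800, -10, 790, 820)), "positive")
})
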