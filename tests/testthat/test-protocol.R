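test_that("default protocol has the block-design structure", {
  p <- generateProtocol(seed = 1, nStimuli = 12)
  ev <- events(p)
  expect_equal(nrow(ev), 25L)  # 1 baseline + 12 stimuli + 12 rests
  expect_equal(sum(ev$label == "stimulus"), 12L)
  expect_equal(sum(ev$label == "rest"), 12L)
  expect_equal(sessionDuration(p), 60 + 12 * 110)
  expect_equal(ev$onset[1], 0)
  expect_equal(ev$duration[ev$label == "baseline"], 60)
  expect_true(all(ev$duration[ev$label != "baseline"] == 55))
  # contiguity: each event starts where the previous one ends
  expect_equal(ev$onset[-1], (ev$onset + ev$duration)[-nrow(ev)])
})

test_that("protocol generation is a pure function of the seed", {
  expect_identical(generateProtocol(seed = 1, nStimuli = 12),
                   generateProtocol(seed = 1, nStimuli = 12))
  # different seeds shuffle the condition order (12 stimuli: collision
  # probability is negligible for these two seeds)
  c1 <- events(generateProtocol(seed = 1))$condition
  c2 <- events(generateProtocol(seed = 2))$condition
  expect_false(identical(c1, c2))
})

test_that("conditions are balanced for any even count", {
  for (n in c(4L, 12L, 20L)) {
    ev <- events(generateProtocol(seed = 2, nStimuli = n))
    conds <- ev$condition[ev$label == "stimulus"]
    expect_equal(sum(conds == "acquaintance"), n / 2)
    expect_equal(sum(conds == "stranger"), n / 2)
  }
})

test_that("invalid stimulus counts are rejected", {
  expect_error(generateProtocol(seed = 1, nStimuli = 11), "even")
  expect_error(generateProtocol(seed = 1, nStimuli = 0), "even")
  expect_error(generateProtocol(seed = 1, nStimuli = -4), "even")
})

test_that("self-report variant inserts an extra rest-labelled gap", {
  p <- generateProtocol(seed = 3, nStimuli = 4, samBreak = TRUE)
  ev <- events(p)
  expect_equal(nrow(ev), 1L + 4L * 3L)
  expect_true(validObject(p))
  # each stimulus is still immediately followed by a 55-s rest
  stimIdx <- which(ev$label == "stimulus")
  expect_true(all(ev$label[stimIdx + 1L] == "rest"))
  # and the event just before every later stimulus is the true rest
  expect_true(all(ev$label[stimIdx[-1L] - 1L] == "rest"))
})
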