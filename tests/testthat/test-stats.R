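test_that("signed-rank test matches the stats-package exact test when untied", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                              correct = FALSE)
    got <- pairedWilcoxon(x, y)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$method, "exact")
  }
})

test_that("signed-rank exact p survives ties (brute-force enumeration oracle)", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    d <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), n, replace = TRUE)
    got <- pairedWilcoxon(d, numeric(n))
    expect_equal(got$p, enumSignedRankP(d), tolerance = 1e-12,
                 label = sprintf("series %d", i))
  }
})

test_that("20 pairs of identical positive differences give p = 2/2^20", {
  got <- pairedWilcoxon(rep(5, 20), rep(4, 20))
  expect_equal(got$p, 2 / 2^20, tolerance = 1e-15)
  expect_equal(got$method, "exact")
  expect_gt(got$Z, 0)
})

test_that("signed-rank degenerate and undersized inputs are explicit", {
  allZero <- pairedWilcoxon(1:10, 1:10)
  expect_equal(allZero$p, 1)
  expect_equal(allZero$Z, 0)
  expect_equal(allZero$method, "degenerate")
  expect_error(pairedWilcoxon(c(1, 2, 3, 4, 5), c(0, 1, 2, 3, 4)),
               "at least 6")
  expect_error(pairedWilcoxon(1:5, 1:4), "equal length")
})

test_that("signed-rank Z is signed by the median difference", {
  x <- c(5, 7, 8, 9, 10, 12, 14, 6)
  up <- pairedWilcoxon(x, x - 2)
  dn <- pairedWilcoxon(x - 2, x)
  expect_gt(up$Z, 0)
  expect_equal(dn$Z, -up$Z)
  expect_equal(dn$p, up$p)
})

test_that("rank-sum test matches stats-package and enumeration oracles", {
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    a <- stats::rnorm(n1); b <- stats::rnorm(n2)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    got <- ranksumWilcoxon(a, b)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$p, enumRankSumP(a, b), tolerance = 1e-12)
    expect_equal(got$method, "exact")
  }
  # tied data fall back to the tie-corrected normal approximation
  a <- c(1, 2, 2, 3, 4, 5); b <- c(2, 3, 3, 4, 5, 6)
  got <- ranksumWilcoxon(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$method, "normal")
})

test_that("rank-sum Z direction follows the sample medians", {
  a <- c(10, 11, 12, 13, 14); b <- c(1, 2, 3, 4, 5)
  expect_gt(ranksumWilcoxon(a, b)$Z, 0)
  expect_lt(ranksumWilcoxon(b, a)$Z, 0)
  expect_error(ranksumWilcoxon(1:3, 1:6), "at least 4")
})

test_that("both tests hold their nominal level under the null", {
  set.seed(24)
  nRep <- 1000
  rejPaired <- 0; rejRank <- 0
  for (i in seq_len(nRep)) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    if (pairedWilcoxon(x, y)$p < 0.05) rejPaired <- rejPaired + 1
    a <- stats::rnorm(12); b <- stats::rnorm(12)
    if (ranksumWilcoxon(a, b)$p < 0.05) rejRank <- rejRank + 1
  }
  expect_gte(rejPaired / nRep, 0.03); expect_lte(rejPaired / nRep, 0.07)
  expect_gte(rejRank / nRep, 0.03); expect_lte(rejRank / nRep, 0.07)
})

test_that("Bonferroni correction is the clipped product and order-preserving", {
  expect_equal(bonferroni(0.004, m = 12), 0.048)
  expect_equal(bonferroni(0.2, m = 12), 1)
  p <- c(0.001, 0.01, 0.04, 0.3)
  pc <- bonferroni(p, m = 12)
  expect_true(all(diff(pc) >= 0))
  expect_true(all(pc >= p))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("effect size r is |Z|/sqrt(n)", {
  expect_equal(effectSizeR(4.32, 123), 4.32 / sqrt(123))
  expect_equal(round(effectSizeR(4.32, 123), 2), 0.39)
  expect_equal(effectSizeR(-2, 100), 0.2)
  expect_error(effectSizeR(1, 1), "at least 2")
})

test_that("normality screen separates normal from heavily skewed samples", {
  set.seed(25)
  x <- stats::rnorm(100)
  sn <- shapiroScreen(x)
  expect_true(sn$normal)
  expect_equal(sn$p, stats::shapiro.test(x)$p.value)
  se <- shapiroScreen(stats::rexp(100)^2)
  expect_false(se$normal)
  expect_error(shapiroScreen(c(1, 2)), "3 to 5000")
})

test_that("demographics t-test reproduces both SD conventions", {
  ages <- c(35, 32, 31, 19, 18, 57, 73, 25, 25, 40, 30)
  ref <- c(50, 20, 35, 41, 29, 44, 38, 26, 31, 45, 36)
  res <- demographicsTTest(ages, ref)
  d <- res$descriptives
  expect_equal(d$mean[1], 35)
  expect_equal(round(d$sdPopulation[1], 2), 15.81)
  expect_equal(d$sdSample[1], stats::sd(ages))
  tt <- stats::t.test(ages, ref, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  deg <- demographicsTTest(rep(30, 5), rep(30, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("cohort comparison detects the embedded HC effect and its layout", {
  spec <- tinySpec(seed = 31, nHC = 5L, nMCS = 4L, nUWS = 4L,
                   groupEffectScale = c(HC = 1, MCS = 0, UWS = 0))
  res <- runCohort(generateCohort(spec))
  cmp <- compareCohort(res)
  expect_equal(nrow(cmp), 12L * 9L)
  expect_setequal(unique(cmp$contrast), c(
    "AcqVsStr.HC", "AcqVsStr.UWS", "AcqVsStr.MCS",
    "HCvsMCS.Acq", "HCvsMCS.Str", "HCvsUWS.Acq", "HCvsUWS.Str",
    "HCvsDOC.Acq", "HCvsDOC.Str"))
  hcMean <- cmp[cmp$contrast == "AcqVsStr.HC" & cmp$feature == "MeanNN", ]
  expect_equal(hcMean$n1, 5L * 6L)
  expect_true(hcMean$significant)
  expect_gt(hcMean$Z, 0)  # acquaintance lengthens the heart period
  expect_equal(hcMean$r, abs(hcMean$Z) / sqrt(hcMean$n1 + hcMean$n2))
  # corrected p is the per-contrast Bonferroni over the 12-feature family
  sel <- cmp$contrast == "AcqVsStr.HC"
  expect_equal(cmp$p_corrected[sel], pmin(1, 12 * cmp$p_raw[sel]))

  m <- buildResultsTable(cmp)
  expect_equal(dim(m), c(12L, 9L))
  expect_equal(rownames(m), hrvFeatureNames())
  expect_equal(m["MeanNN", "AcqVsStr.HC"], "***")
  expect_true(all(m %in% c("***", "-")))
  expect_identical(attr(m, "comparisons"), cmp)
})

test_that("an empty comparison set yields an all-missing results matrix", {
  m <- buildResultsTable(NULL)
  expect_equal(dim(m), c(12L, 9L))
  expect_true(all(is.na(m)))
})

test_that("evidence strengthens with the size of the embedded effect", {
  pFor <- function(delta, seed) {
    model <- new("HeartPeriodModel", m0 = 850, aLF = 20, aHF = 25,
                 fLF = 0.1, fHF = 0.25, sigma = 10,
                 delta = c(acquaintance = delta, stranger = 0))
    spec <- tinySpec(seed = seed, nHC = 4L, nMCS = 1L, nUWS = 1L,
                     model = model,
                     groupEffectScale = c(HC = 1, MCS = 0, UWS = 0))
    res <- runCohort(generateCohort(spec))
    cmp <- compareCohort(res)
    cmp$p_raw[cmp$contrast == "AcqVsStr.HC" & cmp$feature == "MeanNN"]
  }
  seeds <- 41:45
  meanP <- function(delta) mean(vapply(seeds, function(s) pFor(delta, s),
                                       numeric(1)))
  pNull <- meanP(0); pBig <- meanP(40)
  expect_gt(pNull, 0.1)   # null p is uniform on average (mean 0.5)
  expect_lt(pBig, 0.001)
  expect_lt(pBig, pNull)
})
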