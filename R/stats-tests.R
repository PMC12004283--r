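# Exact two-sided signed-rank p-value by shift-convolution over doubled
# midranks (exact even under ties in |d|; reduces to the psignrank null when
# untied). r2 are the doubled ranks (integers), w2 the doubled observed W+.
exactSignedRankP <- function(r2, w2) {
  maxS <- sum(r2)
  dist <- c(1, numeric(maxS))          # P * 2^n, over sums 0..maxS
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(maxS + 1L - r)])
    dist <- dist + shifted
  }
  dist <- dist / 2^length(r2)
  cdf <- cumsum(dist)
  pLow <- cdf[w2 + 1L]
  pHigh <- 1 - if (w2 >= 1L) cdf[w2] else 0
  min(1, 2 * min(pLow, pHigh))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided Wilcoxon signed-rank test as used for within-group
#' condition contrasts: zero differences are dropped, tied absolute
#' differences get mid-ranks, no continuity correction. The p-value is exact
#' (full enumeration of the 2^n sign assignments via convolution, valid under
#' ties) for up to `exactLimit` informative pairs, and uses the
#' tie-corrected normal approximation beyond. The reported `Z` is the
#' normal-approximation magnitude signed by the direction of the median
#' difference.
#'
#' @param x,y paired samples (equal length).
#' @param exactLimit largest number of informative pairs for which the exact
#'   null distribution is enumerated.
#' @return List: `Z`, `p`, `n` (informative pairs), `statistic` (W+, sum of
#'   positive-difference ranks), `method`.
#' @export
#' @examples
#' pairedWilcoxon(c(5, 7, 8, 9, 3, 4, 6, 2), c(1, 2, 3, 4, 5, 6, 7, 8))
pairedWilcoxon <- function(x, y, exactLimit = 50L) {
  if (length(x) != length(y))
    stopData("paired samples must have equal length")
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(Z = 0, p = 1, n = 0L, statistic = 0, method = "degenerate"))
  if (n < 6L)
    stopData("need at least 6 informative (nonzero-difference) pairs, got %d", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tieTab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tieTab^3 - tieTab) / 48
  z0 <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (n <= exactLimit) {
    p <- exactSignedRankP(as.integer(round(2 * r)), as.integer(round(2 * W)))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z0))
    method <- "normal"
  }
  dir <- sign(stats::median(d))
  if (dir == 0) dir <- sign(W - mu)
  list(Z = dir * abs(z0), p = min(1, p), n = n, statistic = W,
       method = method)
}

#' Wilcoxon rank-sum (Mann-Whitney) test for independent samples
#'
#' Two-sided rank-sum test as used for between-group contrasts: mid-ranks for
#' ties, no continuity correction. The p-value is exact (via the Mann-Whitney
#' null distribution) when there are no ties and both samples have at most
#' `exactLimit` observations; otherwise the tie-corrected normal
#' approximation. `Z` is the approximation magnitude signed by the direction
#' of the median difference `median(a) - median(b)`.
#'
#' @param a,b independent samples, each of size at least 4.
#' @param exactLimit largest per-group size for the exact null.
#' @return List: `Z`, `p`, `n1`, `n2`, `statistic` (Mann-Whitney U of `a`),
#'   `method`.
#' @export
ranksumWilcoxon <- function(a, b, exactLimit = 50L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 4L || n2 < 4L)
    stopData("need at least 4 observations per group (got %d and %d)", n1, n2)
  r <- rank(c(a, b))
  W1 <- sum(r[seq_len(n1)])
  U <- W1 - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- any(duplicated(c(a, b)))
  mu <- n1 * n2 / 2
  tieTab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
  z0 <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (!ties && max(n1, n2) <= exactLimit) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z0)))
    method <- "normal"
  }
  dir <- sign(stats::median(a) - stats::median(b))
  if (dir == 0) dir <- sign(U - mu)
  list(Z = dir * abs(z0), p = p, n1 = n1, n2 = n2, statistic = U,
       method = method)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory normality check: the analysis always proceeds nonparametrically,
#' mirroring standard practice for skewed HRV responses; this screen only
#' documents why.
#'
#' @param values sample, 3 to 5000 observations.
#' @param alpha flag threshold.
#' @return List: `W`, `p`, `normal` (TRUE iff `p >= alpha`).
#' @export
shapiroScreen <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stopData("Shapiro-Wilk requires 3 to 5000 observations (got %d)", n)
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value >= alpha)
}

#' Bonferroni correction
#'
#' `p_corr = min(1, m * p)`, order-preserving. The default family in this
#' pipeline is the 12 HRV measures within one contrast.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param m family size, at least `max(1, length(p))`.
#' @return Corrected p-values.
#' @export
#' @examples
#' bonferroni(0.004, m = 12)
bonferroni <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stopData("p-values must lie in [0, 1]")
  m <- max(1, m, na.rm = TRUE)
  pmin(1, m * p)
}

#' Effect size r for rank-based tests
#'
#' \code{r = |Z| / sqrt(n)}: the standardized test statistic expressed on a
#' correlation scale.
#'
#' @param Z standardized test statistic.
#' @param n total number of observations entering the test.
#' @return r in `[0, 1]` (for |Z| within range).
#' @export
#' @examples
#' effectSizeR(4.32, 123)  # ~0.39
effectSizeR <- function(Z, n) {
  if (n < 2L) stopData("need at least 2 observations")
  abs(Z) / sqrt(n)
}

#' Independent-samples t-test on demographics
#'
#' Pooled-variance two-sided t-test (e.g., on age across groups), with group
#' descriptives under both SD conventions (sample, n-1; population, n) since
#' published demographic tables differ in which they print.
#'
#' @param agesA,agesB the two groups' values.
#' @return List: `t`, `p`, `df`, `descriptives` (data.frame with mean,
#'   sdSample, sdPopulation, n per group), `degenerate` flag (zero pooled
#'   variance).
#' @export
demographicsTTest <- function(agesA, agesB) {
  agesA <- agesA[is.finite(agesA)]; agesB <- agesB[is.finite(agesB)]
  if (length(agesA) < 2L || length(agesB) < 2L)
    stopData("need at least 2 observations per group")
  desc <- data.frame(
    group = c("A", "B"),
    n = c(length(agesA), length(agesB)),
    mean = c(mean(agesA), mean(agesB)),
    sdSample = c(stats::sd(agesA), stats::sd(agesB)),
    sdPopulation = c(sqrt(mean((agesA - mean(agesA))^2)),
                     sqrt(mean((agesB - mean(agesB))^2))))
  if (desc$sdSample[1] == 0 && desc$sdSample[2] == 0) {
    eq <- mean(agesA) == mean(agesB)
    return(list(t = if (eq) 0 else Inf * sign(mean(agesA) - mean(agesB)),
                p = if (eq) 1 else 0,
                df = length(agesA) + length(agesB) - 2L,
                descriptives = desc, degenerate = TRUE))
  }
  tt <- stats::t.test(agesA, agesB, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), descriptives = desc, degenerate = FALSE)
}
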