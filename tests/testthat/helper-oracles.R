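# Independent oracles: deliberately naive implementations used only to
# cross-check the package's computations.

# Time-domain HRV measures by explicit loops and hand-written order
# statistics (type-7 percentile formula), independent of the package code.
naiveTimeDomain <- function(rr) {
  n <- length(rr)
  s <- 0; for (v in rr) s <- s + v
  meanNN <- s / n
  srt <- sort(rr)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  absdev <- sort(abs(rr - med))
  madRaw <- if (n %% 2 == 1) absdev[(n + 1) / 2] else
    (absdev[n / 2] + absdev[n / 2 + 1]) / 2
  ss <- 0; for (v in rr) ss <- ss + (v - meanNN)^2
  sdnn <- sqrt(ss / (n - 1))
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  sd2 <- 0; for (v in d) sd2 <- sd2 + v^2
  rmssd <- sqrt(sd2 / (n - 1))
  dm <- 0; for (v in d) dm <- dm + v
  dm <- dm / (n - 1)
  sds <- 0; for (v in d) sds <- sds + (v - dm)^2
  sdsd <- sqrt(sds / (n - 2))
  prc <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  c20 <- 0; c50 <- 0
  for (v in d) { if (abs(v) > 20) c20 <- c20 + 1; if (abs(v) > 50) c50 <- c50 + 1 }
  list(MeanNN = meanNN, MedianNN = med, MadNN = 1.4826 * madRaw,
       SDNN = sdnn, RMSSD = rmssd, SDSD = sdsd,
       Prc80NN = prc(0.8), Prc20NN = prc(0.2),
       pNN20 = 100 * c20 / (n - 1), pNN50 = 100 * c50 / (n - 1))
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments with the observed (mid-)ranks of |d|.
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  eps <- 1e-9
  pLow <- mean(ws <= wObs + eps)
  pHigh <- mean(ws >= wObs - eps)
  min(1, 2 * min(pLow, pHigh))
}

# Exact two-sided rank-sum p by enumerating all assignments of n1 labels.
enumRankSumP <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= uObs + eps), mean(us >= uObs - eps)))
}

# Closed-form Butterworth magnitude response (single pass).
butterHighpassMag <- function(f, fc, order) {
  1 / sqrt(1 + (fc / f)^(2 * order))
}
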