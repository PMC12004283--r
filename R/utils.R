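# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator routes its randomness through this, so identical arguments
# (seed included) give identical output regardless of ambient RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopData <- function(fmt, ..., class = "hrvDataError") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hrvError")))
}

stopConfig <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("hrvConfigError", "hrvError")))
}

# Stimulus-window lookup table: onsets/ends/conditions of stimulus events.
stimulusTable <- function(protocol) {
  ev <- events(protocol)
  s <- ev[ev$label == "stimulus", , drop = FALSE]
  list(onset = s$onset, end = s$onset + s$duration, condition = s$condition)
}

# Condition active at times t: "none" outside stimulus windows,
# half-open [onset, end) inside.
conditionAt <- function(t, stimTab) {
  idx <- findInterval(t, stimTab$onset)
  cond <- rep("none", length(t))
  hit <- idx >= 1L & t < c(stimTab$end, Inf)[pmax(idx, 1L)]
  cond[hit] <- stimTab$condition[idx[hit]]
  cond
}

# 32-bit FNV-1a hash of the canonical JSON serialization; identifies a run
# configuration in the manifest. Arithmetic kept exact in doubles (< 2^53).
configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
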