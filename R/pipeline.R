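#' Segment a beat series along the protocol and extract features per window
#'
#' One feature vector per protocol event (baseline, stimulus, rest), with
#' explicit missing markers for windows the beat series cannot support. A
#' warning is raised when the protocol extends beyond beat coverage.
#'
#' @param beats a [BeatSeries-class].
#' @param protocol a [SessionProtocol-class] sharing the beats' time origin.
#' @param madConstant passed to [extractFeatures()].
#' @return data.frame, one row per event: `windowId`, `label`, `condition`,
#'   `onset`, `duration`, `valid`, `nIntervals`, plus the twelve measures.
#' @export
segmentWindows <- function(beats, protocol, madConstant = 1.4826) {
  validObject(beats); validObject(protocol)
  ev <- events(protocol)
  if (length(beats@rTimes) &&
      max(beats@rTimes) < sessionDuration(protocol) - 1)
    warning("protocol extends beyond beat coverage; later windows marked missing")
  fvs <- lapply(seq_len(nrow(ev)), function(i)
    extractFeatures(beats, c(ev$onset[i], ev$onset[i] + ev$duration[i]),
                    windowId = i, madConstant = madConstant))
  out <- data.frame(windowId = seq_len(nrow(ev)), label = ev$label,
                    condition = ev$condition, onset = ev$onset,
                    duration = ev$duration,
                    valid = vapply(fvs, `[[`, logical(1), "valid"),
                    nIntervals = vapply(fvs, `[[`, integer(1), "nIntervals"),
                    stringsAsFactors = FALSE)
  featMat <- do.call(rbind, lapply(fvs, `[[`, "features"))
  cbind(out, as.data.frame(featMat))
}

#' Subject-level MAD scale of one feature
#'
#' Raw median absolute deviation (no consistency constant) of a feature
#' across all of the subject's windows -- baseline, stimuli and rests alike,
#' so no condition information leaks into the scale. A zero MAD falls back
#' to a small positive floor and is flagged degenerate.
#'
#' @param values the feature's values across the subject's windows.
#' @param floor positive fallback used when the MAD is exactly zero.
#' @param constant MAD scale constant (default raw, 1).
#' @return List with `scale`, `degenerate`, `nUsed`.
#' @export
#' @examples
#' subjectMAD(c(1, 2, 3, 4, 100))$scale  # median 3, MAD 1
subjectMAD <- function(values, floor = 1e-9, constant = 1) {
  v <- values[is.finite(values)]
  if (length(v) < 3L)
    stopData("need at least 3 non-missing windows (got %d)", length(v))
  s <- stats::mad(v, constant = constant)
  if (s == 0) list(scale = floor, degenerate = TRUE, nUsed = length(v))
  else list(scale = s, degenerate = FALSE, nUsed = length(v))
}

# Index of the normalization reference for each stimulus event: the rest (or
# baseline, for the first stimulus) event immediately preceding it.
precedingRestIndex <- function(ev) {
  vapply(which(ev$label == "stimulus"), function(i) {
    j <- i - 1L
    while (j >= 1L && !ev$label[j] %in% c("rest", "baseline")) j <- j - 1L
    if (j < 1L) NA_integer_ else j
  }, integer(1))
}

#' Rest-referenced, MAD-scaled normalization of stimulus windows
#'
#' For every stimulus window: the feature value minus the value of the same
#' feature in the immediately preceding resting window (the 60-s baseline for
#' the first video), divided by the subject's MAD for that feature (see
#' [subjectMAD()]). The result is a dimensionless response score, robust to
#' between-subject offsets in heart period.
#'
#' @param windowTable output of [segmentWindows()] for one subject.
#' @param madFloor,madConstant passed to [subjectMAD()].
#' @return List: `normalized` (long data.frame `windowId`, `condition`,
#'   `feature`, `value`), `scales` (per-feature MAD with degeneracy flags),
#'   `exclusions` (data.frame of skipped window-features with reasons).
#' @export
normalizeWindows <- function(windowTable, madFloor = 1e-9, madConstant = 1) {
  feats <- hrvFeatureNames()
  scales <- lapply(feats, function(f) {
    v <- windowTable[[f]][windowTable$valid]
    if (sum(is.finite(v)) < 3L)
      return(list(scale = NA_real_, degenerate = NA, nUsed = sum(is.finite(v))))
    subjectMAD(v, floor = madFloor, constant = madConstant)
  })
  names(scales) <- feats
  scaleVec <- vapply(scales, `[[`, numeric(1), "scale")

  stimIdx <- which(windowTable$label == "stimulus")
  restIdx <- precedingRestIndex(windowTable)
  nf <- length(feats); ns <- length(stimIdx)
  fmat <- as.matrix(windowTable[, feats, drop = FALSE])

  # one row per stimulus x feature, feature varying fastest
  windowId <- rep(windowTable$windowId[stimIdx], each = nf)
  condition <- rep(windowTable$condition[stimIdx], each = nf)
  feature <- rep(feats, times = ns)
  stimVal <- as.vector(t(fmat[stimIdx, , drop = FALSE]))
  restOk <- !is.na(restIdx) & windowTable$valid[pmax(restIdx, 1L)]
  restVal <- rep(NA_real_, ns * nf)
  if (any(restOk))
    restVal[rep(restOk, each = nf)] <-
      as.vector(t(fmat[restIdx[restOk], , drop = FALSE]))
  scaleAll <- rep(scaleVec, times = ns)

  reason <- rep(NA_character_, ns * nf)
  stimInvalid <- rep(!windowTable$valid[stimIdx], each = nf)
  reason[stimInvalid] <- "invalid-stimulus-window"
  m <- is.na(reason) & rep(!restOk, each = nf)
  reason[m] <- "missing-preceding-rest"
  m <- is.na(reason) & is.na(scaleAll)
  reason[m] <- "too-few-windows-for-mad"
  m <- is.na(reason) & (!is.finite(stimVal) | !is.finite(restVal))
  reason[m] <- "missing-feature"

  keep <- is.na(reason)
  normalized <- data.frame(
    windowId = windowId[keep], condition = condition[keep],
    feature = feature[keep],
    value = (stimVal[keep] - restVal[keep]) / scaleAll[keep],
    stringsAsFactors = FALSE)
  excl <- data.frame(windowId = windowId[!keep], feature = feature[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  list(normalized = normalized, scales = scales, exclusions = excl)
}

#' Run the feature/normalization pipeline over a cohort
#'
#' Applies [segmentWindows()] and [normalizeWindows()] to every subject and
#' assembles the long normalized table plus the per subject x condition x
#' feature means across each condition's windows (the summary consumed by the
#' statistical layer).
#'
#' @param subjects list of subject records: `list(id, group, protocol, beats)`
#'   (as produced by [generateCohort()]).
#' @param madFloor,madConstant passed to [normalizeWindows()].
#' @return List: `normalized` (subject_id, group, windowId, condition,
#'   feature, value), `conditionMeans` (subject_id, group, condition, feature,
#'   value, nWindows), `exclusions`.
#' @export
runCohort <- function(subjects, madFloor = 1e-9, madConstant = 1) {
  if (length(subjects) == 0L) {
    empty <- data.frame(subject_id = character(0), group = character(0),
                        windowId = integer(0), condition = character(0),
                        feature = character(0), value = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(normalized = empty,
                conditionMeans = empty[, c("subject_id", "group", "condition",
                                           "feature", "value")],
                exclusions = data.frame()))
  }
  normList <- list(); exclList <- list()
  for (subj in subjects) {
    wt <- segmentWindows(subj$beats, subj$protocol)
    nw <- normalizeWindows(wt, madFloor = madFloor, madConstant = madConstant)
    if (nrow(nw$normalized)) {
      nw$normalized$subject_id <- subj$id
      nw$normalized$group <- subj$group
      normList[[subj$id]] <- nw$normalized
    }
    if (nrow(nw$exclusions)) {
      nw$exclusions$subject_id <- subj$id
      exclList[[subj$id]] <- nw$exclusions
    }
  }
  normalized <- do.call(rbind, normList)
  if (is.null(normalized) || !nrow(normalized)) {
    normalized <- data.frame(subject_id = character(0), group = character(0),
                             windowId = integer(0), condition = character(0),
                             feature = character(0), value = numeric(0),
                             stringsAsFactors = FALSE)
  }
  rownames(normalized) <- NULL
  normalized <- normalized[, c("subject_id", "group", "windowId",
                               "condition", "feature", "value")]
  if (nrow(normalized)) {
    agg <- stats::aggregate(value ~ subject_id + group + condition + feature,
                            data = normalized, FUN = mean)
    nWin <- stats::aggregate(value ~ subject_id + group + condition + feature,
                             data = normalized, FUN = length)
    agg$nWindows <- nWin$value
  } else {
    agg <- cbind(normalized[, c("subject_id", "group", "condition",
                                "feature", "value")],
                 data.frame(nWindows = integer(0)))
  }
  exclusions <- if (length(exclList)) do.call(rbind, exclList)
                else data.frame()
  rownames(exclusions) <- NULL
  list(normalized = normalized, conditionMeans = agg, exclusions = exclusions)
}
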