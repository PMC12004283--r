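#' Read and write signal artifacts as plain text
#'
#' CSV is the canonical inter-stage format: every intermediate is
#' inspectable and diff-able. ECG records are two-column CSV
#' (`time_s`, `mV`; the sampling rate is inferred from the time column),
#' beat series are (`time_s`, `annotation`), protocols are YAML or JSON
#' with the event schema of [SessionProtocol-class].
#'
#' @param record an [ECGRecord-class].
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
writeECGCSV <- function(record, path) {
  validObject(record)
  tt <- record@t0 + (seq_along(record@samples) - 1L) / record@fs
  utils::write.csv(data.frame(time_s = tt, mV = record@samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readECGCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "mV") %in% names(df)))
    stopData("%s: expected columns time_s, mV", path)
  if (nrow(df) < 2L) stopData("%s: too few samples", path)
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-12)
    stopData("%s: time column must be uniformly increasing", path)
  new("ECGRecord", samples = df$mV, fs = 1 / stats::median(dt),
      t0 = df$time_s[1L], label = basename(path))
}

#' @rdname io
#' @param beats a [BeatSeries-class].
#' @export
writeBeatsCSV <- function(beats, path) {
  validObject(beats)
  utils::write.csv(data.frame(time_s = beats@rTimes,
                              annotation = beats@annotations),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readBeatsCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "annotation") %in% names(df)))
    stopData("%s: expected columns time_s, annotation", path)
  new("BeatSeries", rTimes = df$time_s, annotations = df$annotation)
}

#' @rdname io
#' @param protocol a [SessionProtocol-class].
#' @param format `"yaml"` or `"json"`.
#' @export
writeProtocol <- function(protocol, path, format = c("yaml", "json")) {
  validObject(protocol)
  format <- match.arg(format)
  ev <- events(protocol)
  payload <- list(events = lapply(seq_len(nrow(ev)), function(i)
    list(label = ev$label[i], condition = ev$condition[i],
         onset = ev$onset[i], duration = ev$duration[i])))
  if (format == "yaml") yaml::write_yaml(payload, path)
  else jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
readProtocol <- function(path) {
  payload <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
             else yaml::read_yaml(path)
  if (is.null(payload$events)) stopData("%s: no events key", path)
  ev <- do.call(rbind, lapply(payload$events, function(e)
    data.frame(label = e$label, condition = e$condition,
               onset = as.numeric(e$onset), duration = as.numeric(e$duration),
               stringsAsFactors = FALSE)))
  new("SessionProtocol", events = ev)
}

#' Inclusion accounting from a screening log
#'
#' Summarizes enrolled / excluded / included counts per group from a subject
#' manifest with per-subject exclusion flags, the bookkeeping a study report
#' states as "n enrolled minus n excluded".
#'
#' @param manifest data.frame with columns `id`, `group`, `excluded`
#'   (logical or 0/1) and optionally `reason`.
#' @return data.frame with one row per group: `group`, `enrolled`,
#'   `excluded`, `included`.
#' @export
inclusionSummary <- function(manifest) {
  req <- c("id", "group", "excluded")
  if (!all(req %in% names(manifest)))
    stopData("manifest must have columns %s", paste(req, collapse = ", "))
  excl <- as.logical(manifest$excluded)
  groups <- unique(manifest$group)
  out <- data.frame(
    group = groups,
    enrolled = vapply(groups, function(g) sum(manifest$group == g), integer(1)),
    excluded = vapply(groups, function(g) sum(excl[manifest$group == g]),
                      integer(1)))
  out$included <- out$enrolled - out$excluded
  rownames(out) <- NULL
  out
}
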